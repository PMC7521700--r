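# Glycosyl hydrolase (GH) family -> substrate group for mucilage
# monosaccharides: Ara (arabinose), Gal (galactose), GlcA (glucuronic
# acid), Fuc (fucose), Man (mannose), Xyl (xylose), the combined
# Ara/Xyl group, and promiscuous families active across the range
# (GH1, GH2, GH4, GH30, GH31). This default map is a curated,
# synthetic stand-in covering the families named in the study text;
# replace it with a project-specific curation for real analyses.
GH1: promiscuous
GH2: promiscuous
GH4: promiscuous
GH30: promiscuous
GH31: promiscuous
GH51: Ara
GH54: Ara
GH43: Ara/Xyl
GH3: Ara/Xyl
GH35: Gal
GH36: Gal
GH42: Gal
GH67: GlcA
GH79: GlcA
GH29: Fuc
GH95: Fuc
GH38: Man
GH76: Man
GH39: Xyl
GH52: Xyl
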