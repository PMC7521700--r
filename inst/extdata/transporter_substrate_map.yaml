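# Sugar transporter accession (TCDB-style) -> transported monosaccharide.
# This default map is a curated, synthetic stand-in; replace it with a
# project-specific curation (e.g. from a TCDB export) for real analyses.
3.A.1.2.2: Ara
2.A.1.2.30: Ara
3.A.1.2.4: Xyl
2.A.1.1.3: Xyl
3.A.1.2.25: Gal
2.A.2.2.1: Gal
2.A.1.7.2: Fuc
3.A.1.2.14: Man
2.A.1.14.10: GlcA
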