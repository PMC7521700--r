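# Alternative nitrogenase screen: the Mo-Fe catalytic operon (nifHDK)
# plus the six Fe-only (anf) and vanadium (vnf) nitrogenase TIGRFAMs.
# Accession-to-gene assignments for the anf/vnf models are curated and
# editable (the screen reports accessions only).
TIGR01287: nifH
TIGR01282: nifD
TIGR01286: nifK
TIGR01860: anfD
TIGR02930: anfK
TIGR01861: anfG
TIGR02932: vnfD
TIGR02931: vnfK
TIGR02929: vnfG
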