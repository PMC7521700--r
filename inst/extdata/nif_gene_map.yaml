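# Canonical nif gene screen: TIGRFAM/Pfam accession -> gene alias.
# The accession list follows the published canonical-nif screen of the
# K. pneumoniae NIF regulon; the accession-to-gene correspondence is
# curated here (the screen reports accessions only) and is editable.
TIGR01287: nifH
TIGR01282: nifD
TIGR01286: nifK
TIGR01283: nifE
TIGR01285: nifN
TIGR01290: nifB
TIGR01817: nifA
TIGR02938: nifL
TIGR02176: nifJ
TIGR02000: nifQ
TIGR03402: nifS
TIGR02660: nifV
TIGR02933: nifW
TIGR01752: nifM
PF04891.11: nifZ
PF03206.13: nifT
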