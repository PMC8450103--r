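# Anticodon -> isotype decoding table (eukaryote).
# isotype: three-letter amino-acid code; Sup = anticodon complementary
#   to a stop codon; CAT additionally decodes as iMet/fMet or Ile2 and
#   is resolved by comparative model scoring.
# The 15 disallowed anticodons follow standard eukaryotic wobble
# rules: G34 spared in the seven inosine-using split boxes
# (GGC Ala, GCG Arg, GAG Leu, GGG Pro, GGA Ser, GGT Thr, GAC Val)
# and A34 unused outside them (AAA Phe, ATT Asn, ATC Asp, ACA Cys,
# ATG His, ATA Tyr, ACT Ser, ACC Gly).
# allowed: FALSE marks anticodons not used by the domain's decoding
#   strategy (the 'unexpected anticodon' consistency rule).
anticodon	isotype	allowed
AAA	Phe	FALSE
AAC	Val	TRUE
AAG	Leu	TRUE
AAT	Ile	TRUE
ACA	Cys	FALSE
ACC	Gly	FALSE
ACG	Arg	TRUE
ACT	Ser	FALSE
AGA	Ser	TRUE
AGC	Ala	TRUE
AGG	Pro	TRUE
AGT	Thr	TRUE
ATA	Tyr	FALSE
ATC	Asp	FALSE
ATG	His	FALSE
ATT	Asn	FALSE
CAA	Leu	TRUE
CAC	Val	TRUE
CAG	Leu	TRUE
CAT	Met	TRUE
CCA	Trp	TRUE
CCC	Gly	TRUE
CCG	Arg	TRUE
CCT	Arg	TRUE
CGA	Ser	TRUE
CGC	Ala	TRUE
CGG	Pro	TRUE
CGT	Thr	TRUE
CTA	Sup	TRUE
CTC	Glu	TRUE
CTG	Gln	TRUE
CTT	Lys	TRUE
GAA	Phe	TRUE
GAC	Val	FALSE
GAG	Leu	FALSE
GAT	Ile	TRUE
GCA	Cys	TRUE
GCC	Gly	TRUE
GCG	Arg	FALSE
GCT	Ser	TRUE
GGA	Ser	FALSE
GGC	Ala	FALSE
GGG	Pro	FALSE
GGT	Thr	FALSE
GTA	Tyr	TRUE
GTC	Asp	TRUE
GTG	His	TRUE
GTT	Asn	TRUE
TAA	Leu	TRUE
TAC	Val	TRUE
TAG	Leu	TRUE
TAT	Ile	TRUE
TCA	SeC	TRUE
TCC	Gly	TRUE
TCG	Arg	TRUE
TCT	Arg	TRUE
TGA	Ser	TRUE
TGC	Ala	TRUE
TGG	Pro	TRUE
TGT	Thr	TRUE
TTA	Sup	TRUE
TTC	Glu	TRUE
TTG	Gln	TRUE
TTT	Lys	TRUE
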