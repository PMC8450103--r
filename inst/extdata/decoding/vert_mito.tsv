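# Anticodon -> isotype decoding table (vert_mito).
# isotype: three-letter amino-acid code; Sup = anticodon complementary
#   to a stop codon; CAT additionally decodes as iMet/fMet or Ile2 and
#   is resolved by comparative model scoring.
# Vertebrate mitochondrial code: TCA decodes Trp; TCT/CCT are stops.
# allowed: FALSE marks anticodons not used by the domain's decoding
#   strategy (the 'unexpected anticodon' consistency rule).
anticodon	isotype	allowed
AAA	Phe	TRUE
AAC	Val	TRUE
AAG	Leu	TRUE
AAT	Ile	TRUE
ACA	Cys	TRUE
ACC	Gly	TRUE
ACG	Arg	TRUE
ACT	Ser	TRUE
AGA	Ser	TRUE
AGC	Ala	TRUE
AGG	Pro	TRUE
AGT	Thr	TRUE
ATA	Tyr	TRUE
ATC	Asp	TRUE
ATG	His	TRUE
ATT	Asn	TRUE
CAA	Leu	TRUE
CAC	Val	TRUE
CAG	Leu	TRUE
CAT	Met	TRUE
CCA	Trp	TRUE
CCC	Gly	TRUE
CCG	Arg	TRUE
CCT	Sup	TRUE
CGA	Ser	TRUE
CGC	Ala	TRUE
CGG	Pro	TRUE
CGT	Thr	TRUE
CTA	Sup	TRUE
CTC	Glu	TRUE
CTG	Gln	TRUE
CTT	Lys	TRUE
GAA	Phe	TRUE
GAC	Val	TRUE
GAG	Leu	TRUE
GAT	Ile	TRUE
GCA	Cys	TRUE
GCC	Gly	TRUE
GCG	Arg	TRUE
GCT	Ser	TRUE
GGA	Ser	TRUE
GGC	Ala	TRUE
GGG	Pro	TRUE
GGT	Thr	TRUE
GTA	Tyr	TRUE
GTC	Asp	TRUE
GTG	His	TRUE
GTT	Asn	TRUE
TAA	Leu	TRUE
TAC	Val	TRUE
TAG	Leu	TRUE
TAT	Met	TRUE
TCA	Trp	TRUE
TCC	Gly	TRUE
TCG	Arg	TRUE
TCT	Sup	TRUE
TGA	Ser	TRUE
TGC	Ala	TRUE
TGG	Pro	TRUE
TGT	Thr	TRUE
TTA	Sup	TRUE
TTC	Glu	TRUE
TTG	Gln	TRUE
TTT	Lys	TRUE
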