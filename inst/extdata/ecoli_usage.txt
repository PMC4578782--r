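# Example codon usage table, Escherichia coli K-12 style,
# in the frequency-only Codon Usage Database text layout (permille).
UUU 22.2  UCU  8.5  UAU 16.2  UGU  5.2
UUC 16.6  UCC  8.6  UAC 12.2  UGC  6.4
UUA 13.9  UCA  7.2  UAA  2.0  UGA  0.9
UUG 13.7  UCG  8.9  UAG  0.2  UGG 15.2
CUU 11.0  CCU  7.0  CAU 12.9  CGU 20.9
CUC 11.0  CCC  5.5  CAC  9.7  CGC 22.0
CUA  3.9  CCA  8.4  CAA 15.3  CGA  3.6
CUG 52.6  CCG 23.2  CAG 28.8  CGG  5.4
AUU 30.3  ACU  9.0  AAU 17.7  AGU  8.8
AUC 25.1  ACC 23.4  AAC 21.7  AGC 16.1
AUA  4.4  ACA  7.1  AAA 33.6  AGA  2.1
AUG 27.9  ACG 14.4  AAG 10.3  AGG  1.2
GUU 18.3  GCU 15.3  GAU 32.1  GGU 24.7
GUC 15.3  GCC 25.5  GAC 19.1  GGC 29.6
GUA 10.9  GCA 20.1  GAA 39.4  GGA  7.9
GUG 26.4  GCG 33.6  GAG 17.8  GGG 11.0
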