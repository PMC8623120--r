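# Nucleotide substitution matrix, NCBI layout: +5 match, -4 mismatch
   A  C  G  T
A  5 -4 -4 -4
C -4  5 -4 -4
G -4 -4  5 -4
T -4 -4 -4  5
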