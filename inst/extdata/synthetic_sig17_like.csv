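SubType,Trinucleotide,Sig17_like_synthetic
C>A,ACA,0.00104166666666667
C>A,ACC,0.00104166666666667
C>A,ACG,0.00104166666666667
C>A,ACT,0.00104166666666667
C>A,CCA,0.00104166666666667
C>A,CCC,0.00104166666666667
C>A,CCG,0.00104166666666667
C>A,CCT,0.00104166666666667
C>A,GCA,0.00104166666666667
C>A,GCC,0.00104166666666667
C>A,GCG,0.00104166666666667
C>A,GCT,0.00104166666666667
C>A,TCA,0.00104166666666667
C>A,TCC,0.00104166666666667
C>A,TCG,0.00104166666666667
C>A,TCT,0.00104166666666667
C>G,ACA,0.00104166666666667
C>G,ACC,0.00104166666666667
C>G,ACG,0.00104166666666667
C>G,ACT,0.00104166666666667
C>G,CCA,0.00104166666666667
C>G,CCC,0.00104166666666667
C>G,CCG,0.00104166666666667
C>G,CCT,0.00104166666666667
C>G,GCA,0.00104166666666667
C>G,GCC,0.00104166666666667
C>G,GCG,0.00104166666666667
C>G,GCT,0.00104166666666667
C>G,TCA,0.00104166666666667
C>G,TCC,0.00104166666666667
C>G,TCG,0.00104166666666667
C>G,TCT,0.00104166666666667
C>T,ACA,0.00104166666666667
C>T,ACC,0.00104166666666667
C>T,ACG,0.00104166666666667
C>T,ACT,0.00104166666666667
C>T,CCA,0.00104166666666667
C>T,CCC,0.00104166666666667
C>T,CCG,0.00104166666666667
C>T,CCT,0.00104166666666667
C>T,GCA,0.00104166666666667
C>T,GCC,0.00104166666666667
C>T,GCG,0.00104166666666667
C>T,GCT,0.00104166666666667
C>T,TCA,0.00104166666666667
C>T,TCC,0.00104166666666667
C>T,TCG,0.00104166666666667
C>T,TCT,0.00104166666666667
T>A,ATA,0.00104166666666667
T>A,ATC,0.00104166666666667
T>A,ATG,0.00104166666666667
T>A,ATT,0.00104166666666667
T>A,CTA,0.00104166666666667
T>A,CTC,0.00104166666666667
T>A,CTG,0.00104166666666667
T>A,CTT,0.00104166666666667
T>A,GTA,0.00104166666666667
T>A,GTC,0.00104166666666667
T>A,GTG,0.00104166666666667
T>A,GTT,0.00104166666666667
T>A,TTA,0.00104166666666667
T>A,TTC,0.00104166666666667
T>A,TTG,0.00104166666666667
T>A,TTT,0.00104166666666667
T>C,ATA,0.00104166666666667
T>C,ATC,0.00104166666666667
T>C,ATG,0.00104166666666667
T>C,ATT,0.00104166666666667
T>C,CTA,0.00104166666666667
T>C,CTC,0.00104166666666667
T>C,CTG,0.00104166666666667
T>C,CTT,0.00104166666666667
T>C,GTA,0.00104166666666667
T>C,GTC,0.00104166666666667
T>C,GTG,0.00104166666666667
T>C,GTT,0.00104166666666667
T>C,TTA,0.00104166666666667
T>C,TTC,0.00104166666666667
T>C,TTG,0.00104166666666667
T>C,TTT,0.00104166666666667
T>G,ATA,0.00104166666666667
T>G,ATC,0.00104166666666667
T>G,ATG,0.00104166666666667
T>G,ATT,0.226041666666667
T>G,CTA,0.00104166666666667
T>G,CTC,0.00104166666666667
T>G,CTG,0.00104166666666667
T>G,CTT,0.226041666666667
T>G,GTA,0.00104166666666667
T>G,GTC,0.00104166666666667
T>G,GTG,0.00104166666666667
T>G,GTT,0.226041666666667
T>G,TTA,0.00104166666666667
T>G,TTC,0.00104166666666667
T>G,TTG,0.00104166666666667
T>G,TTT,0.226041666666667
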