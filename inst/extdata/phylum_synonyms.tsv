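name	canonical
Firmicutes	Bacillota
Bacillota	Bacillota
Bacteroidetes	Bacteroidota
Bacteroidota	Bacteroidota
Actinobacteria	Actinomycetota
Actinomycetota	Actinomycetota
Tenericutes	Mycoplasmatota
Mycoplasmatota	Mycoplasmatota
Proteobacteria	Pseudomonadota
Pseudomonadota	Pseudomonadota
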