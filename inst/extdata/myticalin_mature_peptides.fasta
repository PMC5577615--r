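>A3 myticalin A3 predicted mature peptide
YGWPRMPRIPRKPRYPRYPRYPRWPRHPTIYA-NH2
>A4 myticalin A4 predicted mature peptide
YSWPRMPRIPRLPRYPRYPRYPRYPRWPRHPTIYA-NH2
>A5 myticalin A5 predicted mature peptide
YSWPRMPRIPRLPRYPRYPRYPRWPRWPRQPTIYA-NH2
>C10 myticalin C10 predicted mature peptide
GRRRRYRYWRRGYRSWRRGVTIQERSKSSTLNTED
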