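>C-PG myticalin C pseudogene virtual peptide
RRRRRYRYWRRGLTI*GRSKSLPLNTGD
>D-PG1 myticalin D pseudogene 1 virtual peptide
WGRRWRV*IPSPPRIRPWPP*TWPRPKWPRSATINID
>D-PG2 myticalin D pseudogene 2 virtual peptide (exon 2 partially deleted)
WGRRLRIRIPSPPRPRPWPRPYPGPWPRSATINTDQ
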