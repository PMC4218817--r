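>sp001 gene:gA gene_biotype:protein_coding description:polyproline-rich demo protein
MSTAPPPPPAKLVQGRPPGEFTWPPPASNDLKIMHQEAARPPPPPPPPGV
>sp002 gene:gB gene_biotype:protein_coding description:repeat-free control
MKLVNDAQERTWSHFYCGIMLKVNDAQERTWSHFY
>sp003 gene:gB gene_biotype:protein_coding description:shorter isoform of gB
MKLVNDAQERTWSHFY
>sp004 gene:gC gene_biotype:protein_coding description:PPG-bearing demo protein
MAEPPGQLRSTPPGVVKNDPPGAAWYHC
>sp005 gene:gD gene_biotype:pseudogene description:pseudogene entry, dropped on read
MQQQQQQPPAV
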