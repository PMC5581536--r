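>TruSeq Adapter, Index 7
GATCGGAAGAGCACACGTCTGAACTCCAGTCACCAGATCATCTCGTATGCCGTCTTCTGCTTG
>TruSeq Universal Adapter
AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
>TruSeq Indexed Adapter (read 1 3' sequence)
AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC
>TruSeq Universal Adapter (read 2 3' sequence)
AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA
>Illumina Single End Adapter 1
ACACTCTTTCCCTACACGACGCTGTTCCATCT
>Illumina Paired End PCR Primer 2
CAAGCAGAAGACGGCATACGAGATCGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT
>Nextera Transposase Sequence (read 1)
CTGTCTCTTATACACATCTCCGAGCCCACGAGAC
>Nextera Transposase Sequence (read 2)
CTGTCTCTTATACACATCTGACGCTGCCGACGA
>Illumina Small RNA 3' Adapter
TGGAATTCTCGGGTGCCAAGG
>Illumina Small RNA 5' Adapter
GTTCAGAGTTCTACAGTCCGACGATC
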