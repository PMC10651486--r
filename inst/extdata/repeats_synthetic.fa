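>rep001|I-C
CCTCGGATTCCAGACGGCAGATAAACGAC
>rep002|I-C
GGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACC
>rep003|I-C
GTTTAAGTCTTTGCCTAATTTAGCCAAGGACAATCGGT
>rep004|I-C
GCACTTTCTGATGGACCTCCGGCTCCTAA
>rep005|I-C
ACTAGAATAAGTATGCGCTCCACACCTGAAGGG
>rep006|I-C
CGCGGGTACTACTGTACTTTCTTCTAGG
>rep007|I-C
TGTTTTCGGTCCGGCTGAAGTATGGCTCGCGACGTGGA
>rep008|I-C
CTAAAGACAATAGACCGATCTTTAAGGTGCT
>rep009|I-C
CCGTTAGCCTAGTAGGGGCTGGTGAAGGGTCCGGCGCGC
>rep010|I-C
CTATGATCAGCAAACTTTTCACTGTACAGT
>rep011|I-E
CTAGTGTTAAATGCATCGTGAATAATTTCGGTAG
>rep012|I-E
ACCTCCAGTCCTGTACACAACACCAGGACTCTC
>rep013|I-E
CGCGAGGCTTGAAGACCGTCCAGCGATTTGAACCCA
>rep014|I-E
TATAAGTCACTCATTCTAATGAGGCCGA
>rep015|I-E
ATCGCCATAGTGAGTGTCAAATGCATGGTT
>rep016|I-E
GTCGGTCGGTACGCTGAGCTATTAGACAC
>rep017|I-E
TAAAGAAAATATAGAAAAGCGTGCTTAGGCTAGTATAGC
>rep018|I-E
CTGGGAACTTAAATGTGGCACACCTCGTGATT
>rep019|I-E
TCAAGTGGCCCATCCGCCCCGCAGCGGGCC
>rep020|I-E
TATAATCATGTTATGTCCTTAAATTCGGACGGCGCGGTA
>rep021|I-F
AGCTAGGAGTTGACCCTCTAAGTTAGACCCCTCAAAC
>rep022|I-F
GGGGAAGCTGAGTGAAAAATAACTTAGACGACAGAACGCC
>rep023|I-F
CGTCTTGTAGTCGAGGCGTCATCCGATAACGCCTG
>rep024|I-F
CATAGGAACCGTTAAGCTTATCCGGGCCAATA
>rep025|I-F
CTGTTTAATCGAGATAAGCCCCAGGTTAGGTCTCAA
>rep026|I-F
GATCTTTACATGAACTATACCTTTCTTGGAAGCT
>rep027|I-F
TCTAGAGGCGCCAAAGGCACTCTCTCACAACCAG
>rep028|I-F
CACTGGTTTGGTAAATACACCCCGCTGACATACTA
>rep029|I-F
TCCTGGGCGCCGTTCTATTCCTTTGGTAGGCTGTA
>rep030|I-F
CACGTTATCTATTGCCGGACTGACCGAT
>rep031|II-A
TCGTCTCGTACCACATGCCTCAGTACCCACGCT
>rep032|II-A
CAACTGTATGGATTATATGTGATAGACGA
>rep033|II-A
TTACAGGTCACGACGGATGGGTAAGCGGTG
>rep034|II-A
ATAAAGTAAGGGAGTTATCGTCACTAGAGA
>rep035|II-A
GGTTCGGCATGAGCGGCCCCAATTTGAATTCACGGCGCCC
>rep036|II-A
AGGGGGGTAACAAGCGCCTGGAGGTTTTCCCGGGGC
>rep037|II-A
GTAGTAGAGGTATGCACTCCTGAAACGTACAGT
>rep038|II-A
TAGACATTCAACTCTGATGGTGGACCTCCTAAT
>rep039|II-A
TTGTGCCTCGTGTGGAATATCAGCCAAAC
>rep040|II-A
ATTCACCGCGGTATCACGCGGCGTGGCAAATCGTT
>rep041|V-A
ACAGGCGTAAATTCACTGCATAAATTGGTCGGTACGT
>rep042|V-A
AGGCTCAGCATAAAGTGGATTGGAGGTTGTAC
>rep043|V-A
TATTTGTTGTGACACTCGAGCACTTACCCATTACCCT
>rep044|V-A
GGGCTTGGCACCGCATTGCTGGTGTTGCTGTCGTATAGT
>rep045|V-A
AATTGATGGTGGCAACCCCTCAAGGTCTGAACAGTA
>rep046|V-A
CGGTCATGATGAACGTGATTAAGTGCAGTCA
>rep047|V-A
CTCGTGGGAACTTTTGCGCCTCAGTATGGGCAG
>rep048|V-A
ATGGATTAATAAAGATGAATCGAAAGCATCTGGGCTATTA
>rep049|V-A
TACGATGCTGATTCAGACTGCCATTGCTCA
>rep050|V-A
GGCATCCTTCGCACATTCCAATTGCTATGCTTGCTCGCG
>rep051
ATCTAAGGAACGCGGCGTCGAGGGGTGTCTTC
>rep052
AGCGGTTCCCCACGTGTATGACATGGCACAGC
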