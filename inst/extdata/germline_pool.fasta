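>IGHV1-18_IGHJ4
ACATGCATTCTAGGAAGCGCAATCATAGTCTGACCTCGATCAGCTCTAGTGACAGTAGTG
TTAATAGCTGAACCTATAGCTTATAAATAAAAAGATATTGAGGCGGCCAATGACCGCCCT
AGTGATGGGTCTTCCCCCATCAGAAAACTTATTTGGTAAGTGAGACCTGAATTTCGGGTT
CCCTGAAGGGCGACCTCACTGAGTGGAACTATCGATCCCATTGCCTTTTAACAGCACAGC
TCTGCCCTCGACGTTGTCCATAGGTGTACATTCCTCCTCGTTGTACTCACTTGAAGAAGT
>IGHV3-23_IGHJ6
ACACCGACCAGTTTAGTCTGTGTCGTCGTACTGTCCGGCAGTTTCCTTATGGTGCCTGCG
GCCGGCGGCGATTTTTCACTAGTAGTCACAACAAAGATCATCTTCCGGAACTCTGGGGGG
AACGTAATATCTAGTAGAAGACTTACCCCCGAGTGCAATCAGGGTCAAGTGCACTACCCA
GATTGTAGGGCCCTTGGATGACACAGCGAAATCGTCGTTTGCCGGGGTGCATAGTAATTG
ATGAAGGGACCGGTAATGTCTCGTCGCGTGGCAGAGGTAGTACGGAACACCGCAAACTCG
>IGHV1-69_IGHJ3
GGATTTAACTGCACCGGCCAGGCTAGACTATTCAACTAGACTCCGGAGGGTAGTCGATGT
CTCTAGCGTCTCTCCTACGAGTAGCCTACTCAACTATCAACAGGCTTTTACTTTGACCTG
GAATCAACGTCAAAGTGCATAAGGCATCATAGGGCGATCAATTTATTATTCGCTGCCCCA
AACTAATTGCTCCATAAAAGATATTAAATGCTGGTTGAAAGTGGAGGTGGTTAGCACATA
GAGCGGTCCGCCGTCGTGTAAGATCGTACTCTATGGATTGGGTAGCATACACTGGACCAA
>IGHV4-34_IGHJ5
CGGGAAAAGATAATGTGACCTGCCTGCCATATTCGCTAATGGTCTCCTTTGACTACGTAG
TGCTAGTGCCCTTGGAGAGGCTCTATACAGCGCACTTTGTGATAAAAATGTGCATCGAAG
CGGGGCAACTATCGTACCCCTTGCTAAGAAATCCTTACGGCCTATTTGGGGGGCGCCCTC
GGGAGGAAGCAAATTATTAACAATCTGGTGGTACTATCAAGGTTGGCACCTCTTACCGTG
TTTTCGCTGCGACCTCGACGAGCGCCTCGGCGCCGCTCTCGGCAGATGGATGAAAAGTCA
>IGKV1-39_IGKJ1
CTGTAAGATAATCAACATACCGATAGGGAACCCCACTCCAGGGAAAGGCATCCGGTCTAG
AATGATACCACGGGTGTTGCCCGTTGAACGCCAGTGTCCTACGCTGTGCTCCAACTACCT
GGAACAGCCGCCCCCAGCAATCCGCCAGTAATTTTCAAGCAGTAAAAGATCCTTACACTG
GAATGAGTCCACCAACGATCAGTTCCCCTACTCGTGCTTAATCAACAATGGAAGAGAATC
CCGTCGCCCAGATACTTTCCCCTTAGGGCTCTAGGATGGATCATTCCTCCAAAATTTGGG
>IGKV3-20_IGKJ2
TTCGCAACGAATAGGAGTTAGCACCTAGTCTTGAGGGCGCTAAATCCGTGAGCCGTTTCT
AATAGTGCGGGAGTTCATCAGGCGATCAGGGCAAATTTACCCTGGTCGCCTGACCAACGT
TCGGCAGATTTGAGCCCCTTAAGTCTCGTTGAAGCACGACACGAAACTGGCATCTGAGAC
AGGACATTCGCACCGTAGTGTATATGAGACATACGCTGTTCACGCCGAGTTCATCTGATA
CCATGGCACTGCTAACCACGTAACAGCAGCATCATGTCTAAACACCATGGCAACCGATCA
>IGLV2-14_IGLJ3
GCTACCCTAAAACGGCTTCGACGTGGTTCCGGCCTATACCCCTCGTCGGCTACCCTTTAC
GGCTGAGGTCTTGCTTAAGGCCGGATCTAAAAGTCGTAGATGACTTGACAACTGCGCTTG
CTCGTCGGACCGACAGGCCGTGTGCGGACAGGAATAGTTATATAAACCTTGGTGGCGCCG
ACCAAATCTTGAGCGGGATGTGTCCATCACTCCGCCTGCCAAGGGGCAGACGTTGTGGAT
CTTCAAACACGCTAGGTGGCGACGTCAGCCATCTGGAAGTGGAGTATTCCACGTAGGACC
>IGLV1-40_IGLJ2
TCGCGCTAGAGGGTCACTCCGAACACCCCTTCTCACCTCGCTTGTTTGATACGATTCTCC
ATGAACGTTGATTCCGGCACACTAGACTCCACATTTGTGTCAACTCACGTGACCACTGGC
GTACCTAAGATCGGGTGCGGTTGATCGCTAAGTAAATCGCCGCTTTGTTTAGGAAAGCAG
ACCCCCTGGGACATTCTCATCCTACCATTATACAACTATGCACTTATAGGTTCCAGAACA
CACCTACTGCAAAGCGTCAGATTATACGCAACACACCTTTTCGCACCCGGAGTATCATGA
>TRBV19_TRBJ2-1
AATCCAGAGAGACAGATTAATGTCTCATCCCTGCATGACAGGCTACAATGGGGAAGAGAT
ATACTGTCGGACCGTGCGGTTACGGTTATGTATAAAACCATATACGGACTCACAAAGTCA
ATTCGATTGCGGTTACGTCAGACCCTACGCGTGGCTTTCTCCGTCTGGAACATATTTGAA
GACTGTGCCTACTTGGTCACTGGACGCGCGTACACAGATTCTTGATGGTAAACCAGCGCG
CGGAAAATAGTGGATGATCTGCGCAGAATAGCGAAACCGCCTCCGGCATTGTCCTTACGC
>TRBV5-1_TRBJ1-2
TTGTATCTGCAGTTCAATTGGGGCCTCCAAAGGACACGAACCTTTGGACTCTTCGGGGTA
CGGCCACGGTTATTATCGCCTGGTGCCTCAGTTGTAGTTTGAAATGTGTTACTAGCGAAG
AGTTGTTGCAGACTGGTGGCACAGTCCGGGCTTTCCGCTAAGACGACGGGAACCTGTAGG
CCATAATTGCTTCAGAGGGGGTGGCGGAAGGCCCGGATCGGCGCTTCATCCGACTCGTCG
CTGCAAGTTCAATGTCACCGTAAGTTGGCAGCACTAGGCAGCGAGTTCGACAATGGGCCT
>TRAV12-1_TRAJ33
CAGAGGCCTTCAGCATGGGTGAACATTAGGGGGCCGGCTACTACCAATTCCAGCGATCGG
CCTCATTTCCACGGCCGCACGCCCGAAGATTATTACCACCATGGTTTGTTTTATGGGATA
CATGCCCCCAGCTGTGAGACACACCTGCGCCGAAACGTCCCCCTCATACAATGAAGGCAC
ACAGGACAGAGTGGGACTCGCATGTTGCGTTTGGCTTGGCCTTGAGTCTACACGGCATTG
TGCGATAGATCTCTCGTGAACCGTGGAGCACTTAGAAAGCCTCCCATGGAATTACCCTGG
>TRAV29_TRAJ49
TAAATCACGGATACCATGGTCCCAGATCGAAGTTGAACTTTATAAATATACATTCATACA
TAGTCCAAATCGATTACTTACGAAGCACGCGGAACGAACGAGCTTGCGCTCCTCTGTGGG
AGGACATTTATCCCGAGGGGCTGGTAACTCCCTGGAGTAAGACACATCCTGCCAACCACG
ATCAAAAGGCTAGGCCAATCGACCTGTCAGGGCGCCCTCAAGAGCAACTGGCTTACGAAG
CTCAGAACTGCCTGTCAGGCAAGGGGTCAGCAGTAGTATCCCGAAGGTTCCGGTTGTAGA
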