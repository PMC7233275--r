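>A
TTAGAGCTATTTATAAACAAATGAAATTTAGGGACTTAATAGAAGTTTCACATTAATTGCTAAACCATTCTATTGGTACATTATTCAATTTTTAAATTATGATAGAATAGCTAAGAAAAGACTGAAAATAACGTAGTTAATAATGCAAAATTACTACGTCCTAGAAATTACCTATACTTGCATCCGTTCATACCTACTCAAAAGGAAAATGGACCTAAGGTTCTGTTTGTCGTTTAGCATTGTCGATGCAATTCATAGTAGTGTTGACAAGACAAAACCTAGGTATAAGTATTCTAGGTCGACACTAATTAAACCTCTAACATTAATTTATAATCATGATAACTATACTAAATTATTTGTTTGAATTATACCCAAACATGTCTAGTTTAATTTTTTATTTTTACCATAATCAGCTAAGACTAAAATTTTGCATTGAATATTCCATTATTAGAGGCTACAAGCCTATGTGAGGATATATTTCTATCATTTGAGTATTAATGTTAAGACCGGTCAACACAGCATTCTTCAAGGATCATCTGAAACAATTACAAAATAATACAT
>B
TTAGAGCTATTTATAAACAAATGAAATTTAGGGACTTAATAGAAGTTTCACATGAATTGCTAAACCATTCTATTGGTACATTATTCAATTTTTAAATTATGATAGAATAGCTAAGAAAAGACTGAAAATAACGTAGTTAATAATGCAAAATTACTACGTCCTAGAAATTACCTATACTTGCATCCGTTCATACCTACTCAAAAGGAAAATGGACCTAAGGTTCTGTTTGTCGTTTAGCATTGTCGATGCAATTCATAGTAGTGTTGACAAGACAAAACCTAGGTATAAGTATTCTAGGTCGACACTAATTAAACCTCTAACATTAATTTATAATCATGATAACTATACTAAATTATTTGTTTGAATTATACCCAAACATGTCTAGTTTAATTTTTTATTTTTACCATAATCAGCTAAGACTAAAATTTTGCATTGAATATTCCATTATTAGAGGCTACAAGCCTATGTGAGGATATATTTCTATCATTTGAGTATTAATGTTAAGACCGGTCAACACAGCATTCTTCAAGGATCATCTGAAACAATTACAAAATAATACAT
>C
TTAGAGCTATTTATAAACAAATGAAATTTAGGGACTTAATAGAAGTTTCACATTAATTGCTAAACCATTCTATTGGTACATTATTCAATTTTTAAATTATGATAGAATAGCTAAGAAAATACTGAAAATAACGTAGTTAATAATGCAAAATTACTACGTCCTAGAAATTACCTATACTTGCATCCGTTCATACCTACTCAAAAGGAAAATGGACCTAAGGTTCTGTTTGTCGTTTAGCATTGTCGATGCAATTCATAGTAGTGTTGACAAGACAAAACCTAGGTATAAGTATTCTAGGTCGACACTAATTAAACCTCTAACATTAATTTATAATCATGATAACTATACTAAATTATTTGTTTGAATTATACCCAAACATGTCTAGTTTACTTTTTTATTTTTACCATAATCAGCTAAGACTAAAATTTTGCATTGAATATTCCATTATTAGAGGCTACAAGCCTATGTGAGGATATATTTCTATCATTTGAGTATTAATGTTAAGACCGGTCAACACAGCATTCTTCAAGGATCATCTGAAACAATTACAAAATAATACAT
>D
TTAGAGCTATTTATAAACAAATGAAATTTAGGGACTTAATAGAAGTTTCACATTAATTGCTAAACCATTCTATTGGTACATTATTCAATTTTTAAATTATGATAGAATAGCTAAGAAAAGACTGAAAATAACGTAGTTAATAATGCAAA-------CGTCCTAGAAATTACCTATACTTGCATCCGTTCATACCTACTCAAAAGGAAAATGGACCTAAGGTTCTGTTTGTCGTTTAGCATTGTCGATGCAATTCATAGTAGTGTTGACAAGACAAAACCTAGGTATAAGTATTCTAGGTTGACACTAATTAAACCTCTAACATTAATTTATAATCATGATAACTATACTAAATTATTTGTTTGAATTATACCCAAACATGTCTAGTTTAATTTTTTATTTTTACCATAATCAGCTAAGACTAAAATTTTGCATTGAATATTCCATTATTAGAGGCTACAAGCCTATGTGAGGATATATTTCTATCATTTGAGTATTAATGTTAAGACCGGTCAACACAGCATTCTTCAAGGATCATCTGAAACAATTACAAAATAATACAT
>E
TTAGAGCTATTTATAAACAAATGAAATTTAGGGACTTAATAGAAGTTTCACATTAATTGCTAAACCATTCTATTGGTACATTATTCAATTTTTAAATTATGATAGAATAGCTAAGAAAAGACTGAAAATAACGTAGTTAATAATGCAAAATTACTACGTCCTAGAAATTACCTATACTTGCATCCGTTCATACCTACTCAAAAGGAAAATGGACCTAAGGTTCTGTTTGTCGTTTAGCATTGTCGATGCAATTCATAGTAGTGTTGACAAGACAAAACCTAGGTATAAGTATTCTAGGTCGACACTAATTAAACCTCTAACATTAATTTATAATCATGATAACTATACTAAATTATTTGTTTGAATTATACCCAAACATGTCTAGTTTAATTTTTTATTTTTACCATAATCAGCTAAGACTAAAATTTTGCATTGAATATTCCATTATTAGAGGCTACAAGCCTATGTGAGGATATATTTCTATCATTTGAGTATTAATTTTAAGACCGGTCAACACAGCATTCTTCAAGGATCATCTGAAACAATTACAAAATAATACAT
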