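>AluY synthetic stand-in consensus
CTAGCTGCGGGGTCGAGCGCCCGGCCGTCGCGCGAATTGTCACCGCGGCGACCGCACCGGATTCACGCGGGCGTTGCGCCCCGGCCGCTACAGCCGGAAAACTCATACGGAGAGTAGTACCGTCTGTCCAAAAAACTGGCGTACACCAACACGTGCGGGGATCGCCCTGTAATTTACGGCGTGGAGTGCGGCCAGACCGAGGCCGGTCAGGCGCCGGCGGTACCGTGCTTCGCATGACAGCTGCGACGTCGGCAGTCCGCGGAAGCACTTGTTCGACTCTCCCCGTTCTC
>AluYa5 synthetic stand-in consensus
CTAGCTGCGGGGTCGAGCGCCCGGCCGTCGCGCGAATTGTCACCGCGGCGACCGCACCGGATTCACGCGGACGTTGCGCCCCGGCCGCTACAGCCGGAATACTCATACGGAGAGTAGTACCGTCTGTCCAAAAAACTGGCGTACACCAACACGTGCGGGGATCGCCCTGCAATTTACGGCGTGGAGTGCGGCCAGACCGAGGCCGGTCAGGCGCCGGCGGTACCGTGCTTCGCATGACAGCTGCGACGTGGGCAGTCCGCGGAAGCACTTGTTCGACTCTCCCCGTTCTC
>AluYb8 synthetic stand-in consensus
CTAGCTGCGGGGTCGAGCGCCCGGCCATCGCGCGAATTGTCACCGCGGCTACCGCACCGGATTCACGCGGGCGTTGCGCCCCGGCCGCTAAAGCCGGAAAACTCATACGGAGAGCAGTACCGTCTGTCCAAAAAACTGGCGTACACCTACACGTGCGGGGATCGCCCTGTAATTTACGGCGTGGAGTGCGGCCAGACCGAGGCCGGTCAGGCGCCGGCGGTACCGTGCTTCGCATGACAGCTGCGACGTCGGCAGTCCGCGGAAGCACTTGTTCGACTCTCCCCGTTCTC
>AluYb9 synthetic stand-in consensus
CTAGCTGCGGGGTCGAGCGCCCGGCCATCGCGCGAATTGTCACCGCGGCTACCGCACCGGATTCACGCGGGCGTTGCGCCCCGGCCGCTAAAGCCGGAAAACTCATACGGAGAGCAGTACCGTCTGTCCAAAAAACTGGCGTACACCTACACGTGCGGGGATCGCCCTGTAATTTACGGCGTGGAGTGCGGCCAGACCGAGGCCGGTCAGGCGCCGGCGGTACCGTGCTTCGCATGACAGCTGCGACGTCGGCAGTCCGCGTAAGCACTTGTTCGACTCTCCCCGTTCTC
>AluYg6 synthetic stand-in consensus
CTAGCTGCGGGGTCGAGCGCCCGGCCGTCGCGCGGATTGTCACCGCGGCGACCGCACCGGACTCACGCGGGCGTTGCGCCCCGGCCGCTACAGCCGGAAAACTCATACGGAGAGTAGTACCGTCTGTCCTAAAAACTGGCGTACACCAACACGTGCGGGGATCGCCCTGTAATTTACGGCGTGGAGTGCGGCCAGACCGAGGCCGGTCAGGCGCCGGCGGTACCTTGCTTCGCATGACAGCTGCGACGTCGGCACTCCGCGGAAGCACTTGTTCGACTCTCCCCGTTCTC
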