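>MEIS1 synthetic scaffold reconstructed from peptide placements (filler G)
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGD
IAVFAKQIRAEKPLFSSNPEGGGGGGGGGGGGGGGGGGLEKVHEGGGGGGGGYISCLKGK
GGGGGGGGGGEGGSKSDSEDITRGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGPDKDKKRGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGQKKQLAQDGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>PBX1 synthetic scaffold reconstructed from peptide placements (filler G)
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGIGDLLQQIGTIGDQGGGG
GGGGKHALNCHRMKPALFNVLCEIKEKTVLSIRGGGGGGGGGGGLGGLGGGLGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAKLSQIRGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGTRPISPKEIERGVGGIGGGGGGIGGGGGGGGGGGGGGGGGGGGGGGGGGGNF
NKQATEGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGYKKNIGKFQE
EANIYAAKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGG
>PREP1 synthetic scaffold reconstructed from peptide placements (filler G)
GGGGGGGGGGGGGGGGGGGGGGGLKTEQDPNCSEPDAEGGGGGGGGSQTPMDVDKQAIYR
GGLFGLLGLLFGKCEQSTQGSEGGGGGGGGGGGGGGGGGGGKEGKPFFCEDPEGGGLGGG
GIGVLGGGLLGLEKVNELCKDFCSRYIACLKTKMNSEGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGLSILHQDDGSSKNKRGVLPKHATNVMRGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGSSCSETPKTKKKTAQNRPVQRGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGG
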