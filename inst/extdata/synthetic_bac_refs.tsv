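accession	class	residues
SYNREFA1	A	ELVAFLMRKLKFEQGNDALSVWSYRLEAVTKAGPNIRYIVPELGACLYHVLPLRGVKIAARYLNDGLQLSRSNKVNQDRAVNSSMRKLQRLTGYYLRISCVLLDQSHSDWWTNHLQWVARAHKVPILLRGIEMPYLGNPK
SYNREFA2	A	EPVAFLMRKIKFEQWNDALSVWSYRLEAVTKMGPNIRYIVPELGACLEHVLPLFGVKDAARYLRDGLQLSRDNKRNQDDAVNSSMRKLQRMTWYYLRIKCVLLDQSHSDWWTNHLMWVNRAHKVPILLRGIEMPYLGMPK
SYNREFA3	A	EFVAFLARKLKFEQGNDALSVWSYRLEAVMKACPNIRYIVPELGACLYHVLPLRGVKIAASYLNDGLQLSRSNKVDLDRAVNFSMRKLQRLCDYYLRISCVLADQSHSDWMTNHLQWWAHAHKHPIHLRGIEMPYVGNPK
SYNREFB1	B	DFSMADDPDTREAALVNNGENLTMAERVFRAWYEYAGYPLVAKWATFLANYATAEEQRPKENLRALEQTQIISDDEVTPKVLASYSYQGIFLVDGKTPFVNNSSWVHTKVEIELESIIDTPTRDPDIEIHKKNFLTSAWT
SYNREFB2	B	DFSMADDPDTREAALVNIGENLTMNEPVWRAWYEYWGYPCVAKWATFLANYAVAEEQRPKENSRRLEQTDIISKDVVTPKVLASYSYQGVFLVDGKRPFVNNSSWVHTKVEIELESIADTPTRDYDIEIHKKCFLTSAWT
SYNREFB3	B	DFSMDDDPDTREAALVNNGFNLTMAERVFRATQECAGYPLVAKWATFLANYATAEEQRPKENLRALDQTQIISDDEVTPKCRASYSYQGIFIVDGKTDRVNNSSWVHTKVEIFLESIIVTPVRDLDIEIHKKNFLYVAWT
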