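>SEED01
EVKVDVDNGSVLVIEQVPGNKSEDVKVVCLWNITLVDALKHEEREDEKGLRKVKFFRSVLPDAEVSGLLIPNAVLAKIRYDEL
>SEED02
EYYVDVDRGSVLMDECAPGAKSADVKVRVLENPTLVVAGVHEEREDEHGKREVKFQRSVLPDAQVSAMITENGVLYPIRVDEL
>SEED03
EVKCDVDEGNVLYILGAPGLKSEDHKVNTLENSTLVHAGLHTEFEDWHGKEEVAFQRSVLPDWEVSGLSAENGVLAKIMVDEA
>SEED04
ESRVDVDNGSVLVISGAPGLKSESVKVNVCENGWLVVAGQHDYYEIEHCKREVKFQRPVLPDAIVSGLAAENGVLLKIRYDEP
>SEED05
KVKVDVDNGSVLPIENDPWLEIEDVKVNVLDNGALVVAGKHEEREDEHYYREVKFKRSVLPDAEVSGLIAENQVTAPICRDEL
>SEED06
EVWSDHDNGCVLVIIGAPGTKNEDVKMNVLENGTLKFAYKHEERENEHGNREVKFQRSVMPDAEVSGLSAEKLVGAKIRVDCL
>SEED07
EVSVDVYNESVVVIETAPGLKSEDVEVVVLIAMKHVVQGKHEEREDQHGKAEVKFQRSGLPDAEVSGLFAPNGVLAKIRVDEL
>SEED08
EPKVDVDNGSVLVIEGAPELKSSDHKVNVLENATLVVAGKMEEMEDEHGKRCVKFHPSVIPDAENMGWSAENHVDACIRVHEL
>SEED09
EVKVDVDDGSTNVDTGAPGDKSEKYKVNILENGTLAVTGKHEQRENEHGHREVKCWRSVLTDAEVSGLSAENGVLAQIRVDEL
>SEED10
EVKVDVRNGSVSVIEGHPGLVSEDVKVNSLINGTLVVAGKHEDSEDEHGKLEVKFQRKVLFDWETKVLSAENGIPAMIRVDEL
>SEED11
EVKVDVDGESVLVIEGAPGLKSEDVNVNVLEPGTLLVAENHAEREDEHGKRRVLWQRSVKPDDIVYGLSHWNCVLAKIRVDEL
>SEED12
EVKVEVDNASGLPIEVEPGLKSADVKVNILENWVLVVAGKHEEREYEHGKAEVKFQRGVLPDAECSVLSAFYGVLAKIRVDET
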