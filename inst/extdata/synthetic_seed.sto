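# STOCKHOLM 1.0
SEED01             EVKVDVDNGSVLVIEQVPGNKSEDVKVVCLWNITLVDALKHEEREDEKGLRKVKFFRSVLPDAEVSGLLIPNAVLAKIRYDEL
SEED02             EYYVDVDRGSVLMDECAPGAKSADVKVRVLENPTLVVAGVHEEREDEHGKREVKFQRSVLPDAQVSAMITENGVLYPIRVDEL
SEED03             EVKCDVDEGNVLYILGAPGLKSEDHKVNTLENSTLVHAGLHTEFEDWHGKEEVAFQRSVLPDWEVSGLSAENGVLAKIMVDEA
SEED04             ESRVDVDNGSVLVISGAPGLKSESVKVNVCENGWLVVAGQHDYYEIEHCKREVKFQRPVLPDAIVSGLAAENGVLLKIRYDEP
SEED05             KVKVDVDNGSVLPIENDPWLEIEDVKVNVLDNGALVVAGKHEEREDEHYYREVKFKRSVLPDAEVSGLIAENQVTAPICRDEL
SEED06             EVWSDHDNGCVLVIIGAPGTKNEDVKMNVLENGTLKFAYKHEERENEHGNREVKFQRSVMPDAEVSGLSAEKLVGAKIRVDCL
SEED07             EVSVDVYNESVVVIETAPGLKSEDVEVVVLIAMKHVVQGKHEEREDQHGKAEVKFQRSGLPDAEVSGLFAPNGVLAKIRVDEL
SEED08             EPKVDVDNGSVLVIEGAPELKSSDHKVNVLENATLVVAGKMEEMEDEHGKRCVKFHPSVIPDAENMGWSAENHVDACIRVHEL
SEED09             EVKVDVDDGSTNVDTGAPGDKSEKYKVNILENGTLAVTGKHEQRENEHGHREVKCWRSVLTDAEVSGLSAENGVLAQIRVDEL
SEED10             EVKVDVRNGSVSVIEGHPGLVSEDVKVNSLINGTLVVAGKHEDSEDEHGKLEVKFQRKVLFDWETKVLSAENGIPAMIRVDEL
SEED11             EVKVDVDGESVLVIEGAPGLKSEDVNVNVLEPGTLLVAENHAEREDEHGKRRVLWQRSVKPDDIVYGLSHWNCVLAKIRVDEL
SEED12             EVKVEVDNASGLPIEVEPGLKSADVKVNILENWVLVVAGKHEEREYEHGKAEVKFQRGVLPDAECSVLSAFYGVLAKIRVDET
#=GC ACD_elements  222222aaaa333333bbbbbbbb4444444cc55555LLLLLLLLLLLLLL7777777ddddd8888888eeee99999999
//
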