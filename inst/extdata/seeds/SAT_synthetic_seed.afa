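>SAT_seed_01
REYAREAVPAHARVEPLHTGDGGTNSEYDTELKLPIPAFIVEGGIPGHGNGGKDVQVGEGPSEHEKESGMRYPLPNSTGP
DAWDLIEYDFLQEPVASLFYEWMKEKTAADEFITNNPLYTENIALIDTAGLAAEMATGYRPYMARSIDVI
>SAT_seed_02
REYATEAVPAFARVEPLHTGDGGTNSELDTELKLPIPAIIVEGEIPGHGNGGKDVQVGEGSSEHEKESGMRGPLPNSNGP
DAWDLIEYDGLEEPSASLFYEWMKEKTAADEFIANNPKYTENIALIDTAGLAAEEATGYRLEMARSIKVI
>SAT_seed_03
REYAREAVPAHARDEFLHTGDGGTYSLYDTELKLPIPAFIVEGGIDGHGNGGKDVQVGEGPSEHEKESQMRYHLPNITGP
DAWDLIPYDFLQEPVASDIYEWMKEERAADEFITNNALYTMNIALIDTAGLAMEMATGYRPYMARSIDVI
>SAT_seed_04
REYAREPVPGHARVEPLHTGDGGTNSEYDTMLKLPIPAFIVEGGIPGHNNGGEDVQVGEGPSEHEKGSGMSYPLPNSTGP
DPTTLAEYDFLQEPVASLFYEWMKEKTAADEFITGVPLYTYNAALNITAGLAAEMATGYRKYMARSIDVI
>SAT_seed_05
REYAREAVPAHARVEPLHTGDGGTNSEYDTWLKLRIPAFIVEGGIPNHGAGGKDVQQGEGPSEHEKESGMRYPLPNSTGP
AAWDLIEYDFLQEPVALDFYEWMKEKTAADEFITNNPLYTENIALIGTAGLKAEMAWGYRPYMARSTDVI
>SAT_seed_06
REYAREATPAHARVEPLHTGAGGSNSEYMTELKLPINAFIVEGDIPGHGNGGKDVQAGEGPSEHEKESGMRAVLPNSTEP
DAWDLIEYRFLQEPVASLFYEWMKELTAADEFISNNPLYTENIALIDGAGLAAEMATGYRPYTARSIDVA
>SAT_seed_07
REYAREAVPAGARVEPGRTGDGGTNLEYDTELKIPGPAFIVEGGIPGHDNGGKDVQVGEGPSEHEKESGMRYALPNSTVE
DAWDLIEYDFLQEPVASLFYEFMKEKTAASEGITVNPLYTENIALIDTAGLAAEMATGYRPYMARSIDVI
>SAT_seed_08
REYAREAKPAHALVGPLHTGDGGTNSETDTELKLPIAAFGVEGGIPGHGNGGKGVQVGEGNSEHEKESGMRYPLPNSTGP
DAADLREYAFHQEPVTSLFYELMKMPMQADEFIINNNLYTENIALIDTAGLAAEMATGLRPYMARSIDVI
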