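>KS_seed_01
YHILKDAEFKQQCLFGSNARYPKDGGPNDKLIPYRPLACYVLVVLGSINTVCKMSLHSETFSQPNQLVFPAKYYKASLRG
KGDVQYPLEPWGEKNSMGYQFGARANTLNRGHGCDFPECVEVVSSKIFATTTEPSVNSVSELVEFHIKTQPRADNVPAGP
WKRPHTQLVTKPINIMATSD
>KS_seed_02
YHIRKNAEFKQQCLFGSWARSPKDKGPNDKLIPYRNLACYVLVVLGSINTECKMSLHCESFSQPNVLVFGAKYAKASLRG
KGDVQYPLEPRGEKNSVGYQFGARANTLNRNHGCDMPECVIVVSSKIFASTTEPSVNSVSELVEFHIKTQPRADNVPPGP
WRHPHTQLVSKPINIMATSF
>KS_seed_03
YHRLKDAEAKQWCLFGSNARYPKLGGPRDKVIPYRPLACYVLVVLGSIETVCKMSLHSETFTQPSQLVFPAKDYKRSLRG
LGDVQYPLEPWGEKNSMGYQFGARANTVNRGHGCDNPLCVEVVSSKIFATTAEPMVNSVSELVMFHIKTQPRADNVPTGP
WKRPHTRLVTKPINIMAGSD
>KS_seed_04
YHILKDAEFKQQCLFRLNARYPKDGGPNDKLTPYLPLACYVLVVLGSINTVCKTSQHSETFSQPNDLVFPAKYYKASTRG
KGDVQYPLYPWGERNSMGYQFGARANTLNRGHGCDFPECVEVVSSKIFATTTEPSNNSDSELVEFHIKYQPSAKPVPIGP
WKRPHTQLVTKPINIMATSF
>KS_seed_05
YHLLKDAEFKQQCLFGSNARYAKDGGPNDKLDPARPLACYVLVVPGSINTVGKNSLHSETFSQPNQLVFPAKYYSASLRS
KGDVQYPDKPWGEKNSMGYQTGARANDLNRGHGCDFPECVEVVSSKLFATTTEPSVNSVSEVVEFHIKTQPRADNVPAGP
WKRPATQLVTKGINIMATSD
>KS_seed_06
YHILIRNEFSVQELDGSNARNPKDGGPKDKLRPYRPLAFYVLGVLGSINTVGKMSLHSETFSQPNQLVFPAKYYKASLRY
KGDVQSPLEPWGEKNSMGYQFGARANTLNRGKGCDFPECVEVVSSGIFATGQEPSFNSVSELVEFHIKTRPRADNVPAGP
WKRPHTQLKNKPINIMAYSD
>KS_seed_07
YHIVKDAEFKQQCLRGSNARYPKDGGPNDKLIPYRPLACYVLVVLGSENTVCKMSLHSETFSQPNQLVFPAKYYKASLRG
KGDVQYPLEKWGEKNSDGYQFGARANTLNRGHLCDSPECVEVVVLKIFDDTTEPSVNSVSELVEFHIKTQARADNVPAGP
WIRPHTQLVTKPIDIMATSD
>KS_seed_08
YSILKAAEFKQQCLFGSNARKPEDGGPFDKLIPYRPHACYVLVVTGSIATVCKMSLNSEVFSQPNEFIFPAKYYTASLRG
KGDLQYPLEPWGEKNSMGYQFGARANTLNRGHGCNNPNCVEVVSSPIFATTFEPSVNSVSELVEFHIKTQPRADNVGAGP
WKRPHTQLVTKPINIMATSD
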