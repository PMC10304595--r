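>seed_01
SASAVCEVDWCWMIEKVLEMFSNLQPCGRVMITIVNCMKEAYFFTEELNIEKKTRQVVHI
HMRSWSIQFANCNYANSQMC
>seed_02
SASAVCEVDWCWMIEKVLEAFSGLQPHGRVMITIVNLEKEAYFFTEELNICKSTRQVVHI
HMRSWSIQFANCGYIYSQMY
>seed_03
SASAVCEVDWCKMIEKVLEAFSNLQPMGRVMITIVNCMKEAYFFTEELMICKSTKQVPHI
HMRSWSIQFANCGYIPSQMC
>seed_04
SASAVCEVNWCWMIEKVMEAFSNLQPHGRVMITIVNCMKESYFFTEELMIYKSTRQVVHI
HMRSWSIQFACCGIINSQMC
>seed_05
SASAVCEVYWCTMIEKVLEAFMNLQPHGRVMIRIVNCMKLAYFCTEELNICKSTRQVVHK
HMRSWSIQFANCGYINSQMC
>seed_06
SASAVCEVDWCWMIEKVLEAFSNLQPHGRVMITIVVCMKEAYKFTEELNQCKSTRQVVHI
HMRSWSIQFANCGYVVYQMC
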