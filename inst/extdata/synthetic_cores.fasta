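>p25_core
NLLSDKFEKFASNVHELKYINQAFFKPSRKGVQLFFMTYWIESHSCYGHWAKCGLQRALI
CMTFLHVVDFIQGFFVIRNHLPEFTVFNKMDYECKGGPFDQDRNQCAYMGDLHMKTDCNR
QCGESPMHHPGFSLVWSWANYEWYIGAGVGKSGRVVCWHK
>p25_partial_core
GVQLFFMTYWIESHSCYGHWAKCGLQRALICMTFLHVVDFIQGFFVIRNHLPEFTVFNKM
DYECKGGPFDQDRNQCAYMGDLHMKTDCNRQCGESPMHHP
>dcx_core
SASAVCEVDWCWMIEKVLEAFSNLQPHGRVMITIVNCMKEAYFFTEELNICKSTRQVVHI
HMRSWSIQFANCGYINSQMC
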