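>seed_01
TDLSDKFEKFASNAHELKYINQEFFKPSRKGVQLFFMTYNIESHSCYGHWAKCGLQRKLS
CMTFLHVVYFIQGFFVIRNHLPEFTVFNKMDYECKGGPFDQDRNHCAYMGDLHMKNDCNR
QCGESPFHHPCFSLVWSWANYEWYIGAGVGKSGRVVCWHK
>seed_02
NLLSDKFEKFFSNVHELKYINQAFFKFSDKGVQLFFMTYWIESHSCYGHWAKCGLQRALI
CMTFLHVSDFIQGFFVIRNHHPEFPVFNKMDYECWGGPFDQDRQQCAYMGDLHMKTDCNR
QCGESPVHAPGFSLVWSWANYEIYIGAGVGKSGRAVCWHK
>seed_03
NLLSDKFEKFASNVHELKYINQAFFKSSRKGVQLYFMTYWIESHSCYGHWAKCRLMRALI
CMTFLHVVDFIQGFFVIRNHLPEFTVFNKMDYECKGGPNDFDRNQCAYMMDYHMKTDCNR
QCGESPMLHPGFSPVWSWANYEWYCGAGVGKSGRVVCWHK
>seed_04
NLLSDKFEKFASNVHLLKYINQAFFKPSRNGVNLFFMKFWIESHSCYGHWAKCGLQRALR
CETFFHVVDFIQGFFVIRNHLPQFTVFNKMDYECSGGPFDQDRNQCAYMGDLHMKTDPNR
QCGESPMHHPGFSLVWSWALYEWYIGAGVGKSGRVVCWHK
>seed_05
NLLSDKFEKFASNVHELKCINQAFFKPSRCGVQLFFMTYWIESHSCYGTWAKCGMQMAQI
CMTVLHQVDFIQGFFPISNHWPEFTVFNKMDYECWGGPFDADRNQCAYQGDLHCKTDCNR
QCGESPMHHPGFSLVWSWANYEWYIGAGVGKSGRVVCWHK
>seed_06
NLLSDKFEKFASQVHELKYINQAFFKPSRKGVQLFFLTYWLESHSCYGHWAKCGLQRRLI
CMTFLHVADFIQGFYVIRNHLPEFTVFIKMDYECKGGPFDQDRNQCAGMGDLHMKTDCNR
QCGESPCHHPGFSLVWVWANYEWYIGAGVGKSGRVVCWHK
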