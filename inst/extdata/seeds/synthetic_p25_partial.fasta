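>seed_01
GVQLPFMTYWIESHSCYGHWAKGGLQRALICWTFLHVVDFIQGFFVIRNHLPEFTVFNKM
DYECKGGPFDQDRNQCAYMGDLHMKTDCNRWCGESPMHHP
>seed_02
GVQLFFMTYWIESHSCYGHWAKCGLQRALICMTFLHEVNFIQGFFVIRNHLPEFTVFNKM
DYECKGGPFDQDRNQCAYMGDLHMKTDCNRQCGESPMHHP
>seed_03
GVQLFFMTYWIESHSCYQHWAKCGLQRANICMTFLHVVDFNQGFFVIRNHLPEFTVFLKM
DYECKGGPFDQDRNQCAYMGDLHMKTDCPRQCGESYMHHP
>seed_04
GVQLFFMTNWNESHSCYGHWAKCGLQRALICMTFLHVVDFIQGFFVIRNHLPQFTDFNKM
DYECKGGPFDQDRNQCAYMGDLHVKTDCNRQCGESPMHHP
>seed_05
GVQLFFMTYWIESHSCYGHWAKCGLQRALICMDFLHVVDFIQGFFVIRNHLHEFRVFNKD
DYECKGGPFDQDRNQCAYMEDLHMKTDCNRQCGESPMHHP
>seed_06
GVQDFFMTYWIESHSCYGHWAICMLQRALICMTFLHVVDFIQGFFVIDNHLPEFTVFNKM
DYECKGGPFDQDRNQIAYKGELHMKADCNTQCGESPMHHP
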