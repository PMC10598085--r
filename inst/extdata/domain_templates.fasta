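>CLP1_EN
ALSRGILGVKMFNNCEKAMSPGWTRLDVPAAWYVDRIILIWFKQPKVSGLSLIVNIRNAGKLVEQKPRHLFYYGVYYWPSRGVGIKMLRTGSSHFGDTLCRLSVQNTGEL
>CLP1_P
TKLTKGKNVDFVSGSHQRLKGASGSGKTVCVDSIDVIIMASTVPTGTEWGVVGEYIVGIDEHARIPQNSVALITILVFDEQDTRWVEPVVISYALKKFSRAAFRSKINGVRWASLGDFQLAVIIGYPTEEVAVKLYTTMSDDPAGRAEDWGKRVFYGSTLRGHQVLIIHD
>NOL9_P
TELTKGKNVIFVSGNRPRLKGASGSGKTVKVDHIDVIIAASGVPEQTEWQRTDMYIVCIDDHPRIPQNSVDCITILVFDEQDFRIIETVLISYIAKVFPRATFRSKINAVRWASLGDFQLAVEIGYPTEYVDVNYITTMSDDDAGRAEDWGKRVFYGSTLRGHQVNRWHP
>CLP1_EC
SMKYVAVSEKNVVTILDQFVKPGKYCAINRTLQGSGNIFSQGMVGLIFNNLTEFVELVEDWDIVQSITFIIYHNAIQLQCLTTRTQALRNGRLVYGKICAGFFHDRAWFRAFLATPFVKG
>CLP1_EUC1
GSVVDWRKALRIKMQGQVMFRGRIPNFVQDIEYVTPERRKDKCPLVNYNQVIFTCTMVTRDRILWDFDDKRSWSGGQNDSELEAHKGALDSGMTIDSLINYVKFSSGESQLDTIETKAYGTAVRSLLIGPSNGQLNMLCLVGDTA
>CLP1_EUC2
LSRKCEAIKECLMFEQRLGKICHIADCGAICTGGAVLLLVQAGNEIANSMLVCNGSSIDLWATAVRVHLKGTDREPHDYDPLLLFAGTRREMVNAAVDGRSHNVVIFKFTTKSGYKLVYGETNISDHENWLYSGSDIASILWDEGARVYR
>CLP1_EUC3
MSGAVQIGIKRSAKQVVFEFSLQDCNYDSCTCPNSSYISWGMYTQGDQQDLETESRLHIKQWEIRLPGLKEAPLYSLMIRPRFRAKVGTMTNDIQNQEEDKHDEACEKPTSVDAAGAVSYQSKLNVSLTLGCLDMSVKVA
>CLP1_ALC
FNYPRGWILDNRLCVAKDGRVPTEALVYFREGMLPVQYYAWTSVALPHIINLLRGDDYGYKQDMILTADPVNQHDLGAVEVIPLSWDIKVSHAKDATLCKRSGSSITGIDRVESYMEVLDAAVGTTQEVLMVHGQNDPSVEDLSATLLQGHEVFIKIGAYGESPYFELLGCEHQRDTFNDTIVLQAIVSISMYKCRNELEESDAS
>NOL9_EN
ERADSHCLLAKEHIIEEHELRNMALVFYALVKLFSAFAPLKSAILELPRFPYHSNPTDKARMKFLFPQIDVAHNEGRGEK
>NOL9_EC
KMARINRSDQLGRVWDDFDIIKEPRAIKIFIISIILFIALLDRTGKEISKPFKLWILNINCYVHNASQAYHAGGLTGVWIGNVEYSLHDFRLAIYKLGAI
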