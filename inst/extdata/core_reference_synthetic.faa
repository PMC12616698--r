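>HRPKS_ref class=HR-PKS
GAPGEIGDKNNHCGVMQNVQTDVEPKQTPLYCRPGCEHMGDHWFVFVNRRFNVHLWEGIY
KNELIDSGYHQQHMWYDHWGRCHNTWPICHHILSKGDSPMMKWPMPPWKWGPYATYPLMD
FTLGMQWQSPFLWNKVARNSMHPTNIDTRSFAFLRRYSHWMPVWEVLFLIPNRSAKHEWK
AFYCYECTYKAIKCVACDQITYIEACHEFNIPSWASQMEEFCIIISYCSINFMYMGATWF
DGWDKWIVSPMMFVWAFWVVHDAGKHCVASMKDACDDPEINQMIHNNIVHGCHAGARGWQ
QRYDDLGIYIHKIKYWKIQVQMIKGNWAADHRTLYRISYIPPQEFFIPHKPTWKHQHWWM
LERMNCWHSIHTQAHGSYRKASWIGHEDPYTREVPAEWPCRWENDNWVCFARFFVQSMKI
AMTHQMWMHKQRCMEGNRYLHFEYEHRPPPIMVHHILKLEHIVAFTMWELIVQRFHQHQA
GHMALVYHSVTNSMAFPGDLLLEYIVPISYEITVVCSKARKNFGAHSNRPHQKGWRINFR
NKVGVNMDDDKCLLCPLMVYPLQHEKETGSNVSPPDGMVQNWVNKEHGMAYNINDTYNYW
RLAAHGVVQGEVPTFCWGLGGHNVMIQALVDNFHYSFPPIKTFMWMIAVR
>NRPKS_ref class=NR-PKS
CEHQLGIMWKAQNFTMWAIDIWCNNQHKSDGTGMLGIDLVCEEWLQGYRCLAEAHTQECA
EKMYPMKLAENSNVSLCFNTTEYVRLYARHIYGGPAVYYFQHLRMNITPDHKARHTAQMN
MTHHMVYNRMMSIECMVKGCHFGWNDIGKAEAQAESNYVQTLWIGLAMYRDYPSNTLQCL
MWTIMRKMHGLHLIEDIGDAVWQQMCPSVDSQDVCDDIPYVETFDLFVCDKHERMPQRAG
PSWGKDKMRYWMRPADAMQANYKHKWCGLQNLLEATPSTERWYKNKYHFPTSRYATTFVG
CTMQFHIVKNGHTFARCAQDDQISIRNSWKKDEPQLRETISTFDTSCDKFPNNKWQCSRQ
DTYKSAEGDWEQWAFKRLLKAVGLCKHTDRFYNNMGRCFFFTYTFLPGTRFMNHIKEVSY
QVGLCRFNQFVPVTPLKVWKPIKRMWNMVDHSGGQQASLIYAGQFFAHTPYIIVPLVHRV
MTWRAVFWMHACPMTRPTAAPNPVKSSMGRTQCGRPQAAAHHMCYGVLYKVVGMEPHAHG
RLIVRTKGATELVLMTARYYPFIRMEANTTVWLNCYLGWHRNTTWVAIMAFTHFGNCTLH
ICQDPLEKHSHMYFQAAKQD
>NRPS_ref class=NRPS
DAQFTTIENCYWGCHGSWPTKDGMWKREEWICMYVFENECEISRIPYICVHLNDCPITSD
FPCNSPEWQHAHCIAAGWDKHHGMLYWWHILEFAQSCTATERNVWALQLHPNDQAWACYT
NPCYVLAGSTDNGTREMVPTRGEIWDQMWVMNEEFIGQCHLHFFPKHFKMIPSHTFIPFS
DSSKNYYWDADNWDPFNQVVPQFSMYKTPVFQTFIVNQMMYERWWRYKRPKAHILPYGGQ
ADVCMTPSWKKYEFSDCQPGHPDFHFQVWEWFWDSCPKYQNTASMCHGRKWNIDNSSGWS
HMVGHVRYCCNWYLNENTKKAILKNDILMQWRTIICLYDWTSAWHHLTPDCSQFYPAVDR
PYIMLTCTLDEDRKCIKTGNNRPTPNAEWLWVDAWDFDVCVKSIKIVPGLSFIEITILGC
NCMFLAIAETQMPYLIGCQQPATRVDKIWYGEWQTLSYVWEEVSCYIWCEAMTFFLRLYE
HSQGKVCWPYVNSHNVYYLKHYWMAEFYETSNHMAGSWNYQSTLFLYLFERYCVITWRAQ
RQCNSCANGCMPLRWSFCKHEAHPALRRDKMKCTDRAFMGIPAQVESHRTNGQCLDNNGK
LNCHEQMMPVKQWNLDEEWVFDNTVFMCLPISSIWFADHA
>NRPSL_ref class=NRPS-like
HSETLIIYPQAWFSKHFCLYCLNRYSGHWCQRIATHCHWMKDRKSHYERECLYIPNCKGR
SHENSKPWTSRNFYKMDDALAQGHDTHHGQPIYYRTTWRCKNAYLICCWQDGRMEYVPCM
FIVCKWCNIYNPFDCEFHTQPVVKVGKDEYFGPMKTGQSVCTPEAFDQKWCDFFTTFCKD
NAKFHYAKWPNTSHYLYRRWRVTDIIQRGTYQAMLWYVQNENMGAWQSFHMLVTDFHNTC
CFYEDSQAHCDVHYYKTGCKWNMYKEDALGWHQEFFKKYIMNEPRIMYQQMMDAAVSFVA
NWFAEIGWFNDIHDTKPETWLATRDLAQYKWCTAFESHGKGRPQIFWYSGVPWEEDYTDR
PYFKLVTRCGHTHVYSSANMFTDKPFCKLPYGRHKWGQWTHNTLHQRFFWFVFRWGLNAG
DFHHFMQDEPTRWIFDEHDWFMDRMLIWDCMPLHDALYIQLWDSTQISQWKKMYEDLKSN
CSKVPHIYMTVHFYADTYEWINGPVCANKKGHDPDKQNTS
>TS_ref class=terpene_synthase
IGGYAPAWRCMFYLISRTDWTWKLPGVYWPRLPKFHMFGAGAPDEWSCLTSHHWITCNLQ
GPHEEVFEQSYQTTFNNKPTYVLGATLEHSDIVIAAMAIWNVGPIIMEKNRNEKEACIMT
LSMWHFPHHVYTANKAYNVIKREQPFLFSKANVKMRHGFGAMAYSFHCYYSDMIPQERNE
WQIAWPVKRSLLWCGICISEEFPFMTAYYDGSHCFTEQDFLQLWWHKRTDRDPEILMTMK
SDWKSTLWAVICAWIKRWDPQKVAWQAFLTWQTPQKMHVYWPERWGHGNRMYPKNMFKYM
MNESALVHIKLTMEAYHEQQGHVCPAKNAC
>PT_ref class=prenyltransferase
HQMDIFLHICPEGPRSPKMIWRHVPFVRVVCNSKHNAARHWETCQHWPMLTNMLVQPRKF
NWYFPQFRVFRFQSNPKYETWTTIVGLYWDERQVMMLPWMFWECEQYKDSWEIRIVNVTY
EKKSTFNQFNETMDHMKDPMLVHWDKHCQCQLNLLKKHFYDRADWDWTIFATWRYIKTEW
YAKGYMMQIIDGPEHFGPYTIFENYVYKICQCMPAHNPCPVLETQMHHKDAQKWFFSQEF
MANRNYNIKLVPLIGLFLATTYLFLCCLLTLWPFCKFETFRHFPMMVVSRCWHRMHWVAK
TARYTPPPSMDHSGNTDITTWNFGEKHYYWEMVALKSFHVCEWGQLYQDLIVQLYKEYIF
IANHCETELRDCKSTQFLHHNQLLEMFASGKWIYMTAIKGNLGLAKFTESGKISLNGQCA

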