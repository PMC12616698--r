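>ALS1
DFKSNHTHHQALNHRGWHKIGLSNSYMNACNFEVHWTARCDAGPKPRNGKSEINRYKICA
HSSNWRINWSMSCWTLTIFDQSPPENIRSWVRALAQCFIYQFEHIMTTSFNPELFLGETP
GQSDSDLFRIAIQDFYHNTDNGTKTSAIHPEMECGAFCPRDVAQFYRIMNFDEPNFNSMN
PKADGEQARVCCGTRLKEHIIPLYQDFKVFDWKDTNHAIDKQKDMCHACENRENFCPDNL
NQKCNYIECPKATHWYDTIGFKHRLCWWIQVHKVHSFNSQQGMQVISFYMYEPCGWEPAF
CYNQSGCNKYWQPTGQSYVHGAPQCCNYFCCNTCQPHGEQNCPVLLAQRVHWYRYPAENV
EKMQLEINLRAHKMCCRQKKCLHQNMMCEAQWNPQFMWACIWAGEPKDCIWHCIYQRGTE
VLTTGAEGSPAWCRVKPWMLWTHPEYIFHSYAMWHDDQFLMFYMIMGRAQPVAKPPMRRK
EAWAFCDNSHCTSHWMPIGMRAAHDQFCSLPYLETHGLRGYMFRHIHGFLLIEFYGNCLW
PSPTQYPMRAESNFWTQKMI
>HMGR1
CFGMETWHAHMWAMMNFVFRLLNNMPKDDFDIRNNQMHTDPPICMTFNSEAMFEWTLQWQ
GYMTANRRPKVMGRKYMRQEVNEFTIIYSWMGVKKHNMGMLDLFGVHATGDWNDLSQYIK
NQKAETQFCTLHMEWFKHAVMCCCAPMPDCQYVCADCFLGHKDIMAPQFKIRHPQVYAQP
HNIMLMMLTVLFAWEQTGRHNPIYPGNHDVDTIQGCWGKDVCGLGCQHEYNFQSVICHHL
HHLDVPRFADQIQAPMIVWPAMYYPQVMDWAMMDYGTMWLFVSNCKMMCDIPAQRDQMVN
MHYELLRQENCLLFDRHFFLLGLRFHELCSELIQPYTIMWLWWTACCPFYKGLQSTHLQN
WHKYPSETMNWQADMPGPEPLGYGGATSAMNILQYEVTTKIMTCQLLKNTPCYVSPFNWN
SVSSELVDHKSNMLGQDQLKFVDWSHHNLLSTDALTGVNQSRVKRSRNQNDYILFRRSMT
IDYPNMKWDTIQEQCGHYGRKLEMYLPMRQNVCHRPPKKA
>IMPDH1
HKKTCTMSDKMGGNNVSHMIPCDDVQEWVATVFIFYWTDWSTRDVLDMCMVCTAWRHQLD
IIQLRTMQYRAMNSWYNLHAHGTINPNENIQTTNQTIHLWNTWWGYWMKANQWGQRLDWL
QKPRLQIHYEKVDQCGRNWVQALTDHWEDKENFPFSYAWVVDHQHIEPDWTIKYYVGDTH
DLDMHQRPPNKGALHLDFDFMDISEFDWDDAGEDGNCTTEYNGYIQIMYSGKMLMMLKMI
FLNDSCVQFKIIQMKEQWSCNWIYCKHMTEGLDYLHWETNPTEAWIPHKLWSHTIFYAKA
RFMQIFVPTVTRVTILSVDPVNMRLSWIRKHLGIRPQIRNVGCTRWREHTPMQGFRSDYF
CTCRSLTAQYYNVMRYHQKPNYNFPHLDFKQFQICCEYEIMIGWQMLMGKAYVSQNDWID
ESDDARTYEEMWFVVAQDDDEAKWKKIEWKFYLELKADVHVKKESKHGFKDIDHFEFALT

>ADSS1
TEGIGMSREWCKRKVLAIVENNYYICNTSMWGYNSYSFMKSHTIKRTCVHKCRPPCIDDQ
QRVIFDSFCGKDTWQAKNVANHCKFMVTEAKVDDTEAYVYFNHSKMWAAWSHAHVWNVPK
QVFPICASPDMQHQPITFVCKESEYVYCNQMPIFKTCQWLLVCYTFWYDQYKDVAMMDNW
GLTSGDIHDCFFHLSYTNRQIESMYCTKFICAINQAPMVFAFMQASSYCECFATHWQNAV
IPINQEEYKQIEGKICKPNLYLWRVVKDRKVQIVSSERHVLAWYQRAMDLHITFDIGPTT
GTSTMDSQWKCGANFKYGGGRKICLAWGRWHDNVCSKMSITHPRARQAKAFNKNVEPCIY
CWFWNKRHWWLLLSSFRNEYVVANSLHYFQEGAYIAISSREDFGSLNGMNTPRVAGHVAA
FQKYDHRWRY
>PSMB1
NICVVKAWLMINVLKCWIKWIQSKTFYKPWVRHKSHIWCVADCCGWRMMNQKPVVWLKNP
FYACCCMDLNGVNLTQVTVKKQWCPQVVWDFSYATLVDTEFQFDRKDTWKNWEYAQPFEF
HYRCQCSFSCYNASHYGKTGTRYMNFMHKITWWWMNHFFYKMNYKCRHCIHSENTNQHSN
MHPAYPGPTGHLYWTQIGWYTERQMRLLSSLRHIQEVTVRALIERRPFTIDFFWYGIWKH
YTLFPIKCIIWNWTHEPYVRKSSTHTITKPYSNRAPFTVK
>DAHP1
CICMPWAHTMLSMRYACMLPGCDNHWEDVAEFTMFMGFPAYMDARVEPKLWKTWAPSEVQ
LFCCMPIKMTFHLAWAHPLYKKQFIIVGIIACYCVVWIPKLRAILEMKCLYHLNMHEISN
GPWCRMIPIDNKQATHNKELHFLHETGRKIKLNKSLKFFLQPDLPAIWPRMLFVMIFKWA
AEAWQNHVRIWIPGFENMNNNYYADCINHQYTCQTNRGCVCSSNSQHGQPTHIECWKESQ
EFCYFAIHLEREDSCFGTRMQKWGAVHTGAHCKHANPTQICELANFCWDFNGMQCMTQNN
AMNKDIAKVICWNEAKVLYLDDWADWTWRDSMIGNAGYETSTRKKCTIVEDISVVLCFRD
QFYGTCCRPN
>SUR2
WRMWIGPISAHRFWKMDPCKMVNQWISCKVGGNDTHWYEQDKQNTCWVCPLSVQLACPCL
IEMCHKYKLGIGMQHHWYCLRVMHRPRFIRLHNRWSNWHYQMDIWFYHIHKMIPWCWITD
RLGRATVRVFDECCNCWTASQVGNFVCNPIGFNKHVFLYGTRRLEIAMAYMTANSDDVHW
MAKHNARGYSMYEEATDGDPRFSTSPVVGCGCPTCLKAATQHDMSDQQYCNTSWEGRAEN
PGMPQIANVSLVSVFLESQHLTVTHHALHGKMYQKCWKYNWVATVSKAFFDFKVMYPNTI
MEMNFDYPYFQICWKWLEFTDDYSAWFHRN
>TUBB1
ACIETEADAPHYMIIHWNIFFVNYLFHHLRIFHMWCHYMKGKFVYFQENHASCCFKWFQD
HMCMFYTWIYIWTCRYQMNKQEVFMRFMLHCTAWSKFAGDMICYAWDLQHGENMVSVYPY
NLSEIYKIASWTRSNNGSVQYEFHTQCWFTWKQISYNLEMMNEPNLSFKNAKTDTKPSYA
RDMRTIFQMYEDFLHNEFLVQRCSYQWPHECVYNVYRYHRWINSTDTDCQLSSWDNTDFM
EERCENNDPESPYTDVTVCMMYWKHRNWVHHPMYANCVTGIGFACCYYQEKRWFLRFYVA
TVPGFNNRHMDTKPFVAACDKVCQRAQQDIAYATCVCKTRRWPVYWKWTVFAVGGMDRAE
NWKQEGTHRISWENSCHMHRITKKAEASHDWPYYTFLRADMDWEDIQSMVNREGCNRKEA
YMIKEVQLKETRYKTLWEQYMFITG
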