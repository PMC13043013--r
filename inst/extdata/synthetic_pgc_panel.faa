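>SYNPGC001|crtA synthetic reference protein for crtA
KVATADEIFGLKHMEDGGDQPAYLALADRVEGDAKAVRQVGAELLIFADASLNLAVAKSKIKVRFSNTDVNVAVQFVLGSEAGGYMSRFYSPIAPDASGFDSFIQIGHQLDKPARSKTISDSKEKAAGVIFAFRRLQFALPPSNERTTA
>SYNPGC002|crtI synthetic reference protein for crtI
PSFNMSDRDDRINRVNGLKPSALRGKNFGAEDLLITSGRTPRGKELDNDWVPNKLIGITSCFINKKIGSIASPAVPGIPILVAFYWKAHSVASCALYGETTNASTADPELNSSHHDSERV
>SYNPGC003|crtB synthetic reference protein for crtB
ILVPVEFRLTRTKEIDMGAWPTHPPDLFKNLEDLYDVFGSKNAGRKTLITFTDTDNGVLKIFEIQKTETETGLISQVVKAPAMVGAFGEVEVEDGFEVMWKFERLARGNQSYLENVLGVIPIMSFYVLLDALLKMTRNALLLGLEPQPEAETQPRQHYLSKVGNARVCQTDSIRGQ
>SYNPGC004|tspO synthetic reference protein for tspO
TNNDDEMERGYLKQSSDELQAHLLYLATLKQVLAKILVQVRAIVQQTADMDLAIEFGTAELLLPNFDAYSQQVDVHLLSEETMIDSGQGIVLGVKLQDADHQDTEQ
>SYNPGC005|crtC synthetic reference protein for crtC
LQREALCFTTSSWLEVKGGIFRFAQQAGVLSPILSLALVTDGANMAYKYTDTNSPATQMELAHLLQNFVEREKDSDMPLGARLLRMDKIADGYHYFAGTKKGTVRIVIFQEVFAEDSFLLNEPILPGLSTAALNSMIPREEVTLLNGLSLIPLGRGAEARLPLGTKGIMKQVLKVDSTGTVLA
>SYNPGC006|crtD synthetic reference protein for crtD
RGVNIILEKQTNAKSPREVLILFKGERGCCLRFAGESALLFKHLSSGGSAWFHVPGSGQVPSIKVGPAAGAASDKNGGVGRGRGLTDPDHDTGEADLEKSPMG
>SYNPGC007|crtE synthetic reference protein for crtE
KFRVEGIVNGTGETGRMVVHVSLLNMGGKPTRKTEDSIEQGISLDKRSQINESIEFSIAYIVGSGEIAKNAYEKAYAVDIKPRSKMAALLAHAVLLLVPNQDEYHFNEIREVECGDE
>SYNPGC008|crtF synthetic reference protein for crtF
VAFYPKKSWLAQAKKVSEAEKPHFAMLVPAVGNPLLMADVLLAKRVNSLMACGEGQLIQRFFTDDLSLGFSLSLILFGDGGKNDETARRSCMVAKVPELLQKAKSANVEEMLTEKKVFDPTQMPFAGFRKAGLTEEGHGSNELLLTGGTCGTGLHSAKLSTLLDAFSGKYSDEFVCATNMRARLILFHQHMGWRE
>SYNPGC009|bchC synthetic reference protein for bchC
NFLKARVDLKKQQFMGVEPEPKLLEVKVLHLGGFGSKRYGQPKCIHRTIDSYSDQIYQVEVADYWSRNSSSRPLTDILMHDKYSADWTRYVQLAGTEISIMCTQSGIGVMAMILFFTMTSVTEADVTMMYIWQLAITAKPGPGEARSVDAGTCDIEKSLAYMLFEPAAILGKYNNKGDDGLY
>SYNPGC010|bchX synthetic reference protein for bchX
TPQVRMLFDCFEEKLSLLDENTDFLGVKLLAKTYRSTKTNPIAELRPAFPVKRAQVRKGFVAPVECYDVKEQELPQNPVGGIGTLAVELKRRGDEDIQPSAPYAATFDIPRDNTLSSQMIENEATLIEVPEGCEGETSHATLKVQPNIKMSDADEGIATTVHKRNLT
>SYNPGC011|bchY synthetic reference protein for bchY
ARTFFQESKKAKPSDSLQIGFLELILDVCGKVRDKAQDEIVAEFSREGTENSMYEEDDKMEADKPKIIPEKWRHLDNGYSGDDSGLDVSRGGLGLAAVCTKLKCEEVRDKFESYSTEPMWNVWQYGQKGHLFFATNRLPRAMRFEILETTRLLKT
>SYNPGC012|bchZ synthetic reference protein for bchZ
YIQYSAVFHGRNPCKIENMSFMFEYLNVAKFADAGSAFQWFLAFWIRESYVIFRNQSMAIVVGVLLYHEALLPERGVSAVFTEAQHQTAQVLKVNASSDKDITSPTIQVKAGMWAMTPPGDLEYTELRANLEAPLEAFIPLSI
>SYNPGC013|pufB synthetic reference protein for pufB
ALQSAMQVEYGPAYVAGTFGIHKRPLPISDNSHLLIEYTTSRNAAKKAIANLDSGDISIFHRGASNMEPLEGFKMRDNFSLNLASAFIIVSANRGLSYIES
>SYNPGC014|pufA synthetic reference protein for pufA
KDFSQDINLNLGGVILSPFTATAGGVEDELRRSINQPLDNGVGVFIVIPQCQPDLFPNGDVATCNFLNEVAVNKEFGNIYLAQSMTNMKEPGSPMTDISWLCLINAVAKGSIPSLWKAEFDILGPLKATKQYGKLVALEKRSSAPSWHTKPQTPPFNCLARSKLGE
>SYNPGC015|pufL synthetic reference protein for pufL
PERCEVKAAVAISERNVIIQTPTSTMVMVITETSSPRWYIGSPFEVWKSDIGAIQNMDSFLQQYVVVQDTPEYKLKSYIAKVVVKITLVHPKTHLLARGGELIKLFQSRTQDSALYTGCFGFHYTIENFGWDPERDYPMALPPFNNNGLPDIPKDDGNDKFTHTIVIILLHRCLIGGTLETSMDKRYNLITGGKRVILISPFLWLPPNAAITLVARTLKRRMAVFHIAFLGCAQQNPITIEAEPPEKNDQVQKFFSFHGRPGDLLSSGKAREFE
>SYNPGC016|pufM synthetic reference protein for pufM
DAKLEKLYVNLTVLNVYGFRTKAIGVETRQWDTGATNNAKITDDGSSKMPGPEVTNTEADIAQVSVEVKRKKVFQVEAYAKQSVLNDEGLEIPLGHREPAGRDTNMAIAAAETTVSSVANTRKHVKEVDKGPQTGPTVSEQGAQGWAKNINCTVKQLEGAEAVGFINEQLQRQEEGHFGENVPQGKSRLMRDHYMLNNIEIVGPLPTPPGEKTGTKGCEKLYERGYLIKWPSKPSSGGAITVNEAVPYVKGSGLACARGSYFIMDKADLVKKKFKPVVAKITRPNGNLKISLESIQFVLCYTRLDIV
>SYNPGC017|pufC synthetic reference protein for pufC
LEQEDRKIFDKENEPHLDALETHGKGEVHDGKATSNALSRLLLLERRIPSRGEVEEAFTLQAPCDPVKSIEFVFPGASKRPMFVGCGEARVRTAYLRTVCLEDPESSLLPLDAKASRQNNEEATFSKTATVSHPLLKVGTTRILFLASSLLSANHVVVFITLEPKEQPLNRLW
>SYNPGC018|bchP synthetic reference protein for bchP
VAELQVTETFGLGIGFGTPMMARDCLIEFIGLRGLMIDIRQGFAHISAHKKQTQERWADTMRRDAEKGKWAEQPRIPYTVRVQIRPNAFWHAVRLHPRYKWHLQVAATGHGNTAQANGDPIPLENDQGPWDCPTGPLGIRKLGENKVDLRLVSNLRPIEDNVVEVETQRHNKAKLVRDDITPVLDTRRFAEEVGKFRPDA
>SYNPGC019|pucC synthetic reference protein for pucC
IVFPTMYIGIKNQVPLIRSKAVSAVRCVMEKFYNVNYGQLAPLFSQTLRKMLGGFSMGKAGASILIRDHTALVENAIMDLGGPNKEVDRSQAWIQDAYNTQSDFTS
>SYNPGC020|bchG synthetic reference protein for bchG
LLGVGEMGMEVTPQVRADTDPSWHALGPRANLLGSSLGLTRIKVEHENEPAKLHKDPVSRWLIPLQAPTCGLQLMFKIDVLTHEVSVKAHERAQMPVFIEQSLAEAKGDEITTKTKHLEDDSENADGITYTTNHIGVPWLLSATRKELIGGTEERNLALWATRSKIQRILDGDTAILFAWNIELSGCIS
>SYNPGC021|ppsR synthetic reference protein for ppsR
NKPEGYSEGIPAAKPLAGRRADDELGMSRFETHREEKEHYHPTQEKAKNIKNLKYLVKSRVDGGPKIRELAPYSANEKSQTVFKPRFKSELADCREAQGAISELPLTNQSDTVGVAATAVRVMSGASLFQKMKARNHVKEFQDFEYPMGFEHVGNENSDHQAMIIKIDGVISKSKPTLLEGVHQMASTSP
>SYNPGC022|ppaA synthetic reference protein for ppaA
PIFEFQEIRGPLVMGGSGETIEGNEQLIIFYGTPPPRVAVQGENEKLMSAPERTKTSRPNTEFEMSPEDLGTIFVTEIRLLVMSAQHVSAKEAVKTESQRQMGEVNLNIIEQINYETNRNQPNLGSAYKIRTTCRQLNVMDKEGEGSTGDWLEGRVIPGLPAITTSTTDEYYFAPAGSL
>SYNPGC023|bchF synthetic reference protein for bchF
QKPDVISKVVAKTEADKVTEMNNAVSVTNVFGPINSRSIYRIAMYEFITEYGRADLNIDDCTILAKYWKFLDKDMFEYEKLHPRVMVKGIGSAAHLKNEMPGFSTCFITTKNIIVTNEWALDILISAGNDFGGELTAALINFLASQPADEGIFLNPFNVFSTLGQEKARPV
>SYNPGC024|bchN synthetic reference protein for bchN
RKAQPNMVEQLEEEQNNNDLTIYQLVDHIDTAEMHPKKLKDSQTTCLRNTMGDYEMNFAFVNNAIRGIEANLRAVGAGQFSTAYPGILIYQEEPHGWAKIDRKQRTLPPIDEDVTEDPFEVYHENPAKSNTAGNDEINVKKTAPSDANTGT
>SYNPGC025|bchB synthetic reference protein for bchB
GSTFALTVIGMVRNNYINIQNIQAVPNGLDQVKQYMWESNVFDWSAGYRGAKNERNLWGRARWELLDAKRISGLLKDDVVPGQSIVLSVSADQIHYGYQLASWTIPDTQSLLDARNAYVVKVVISSLITM
>SYNPGC026|bchH synthetic reference protein for bchH
ILDAEGDACASGAIVLLEPDPLFYDCCWLGPDARSHVVSRRLARKPGFRTALYECYIGTSELLFLIEEVSMVPRTRAGGAAPLRKKAFRMAAKHPQVGFLPALLVHDIAVYGPILYMLATQHLGADQDTDVIGPTPGRRYEIYQTPTRGASIALTTGIAACRTSDVRSFDRNLEFNVRE
>SYNPGC027|bchL synthetic reference protein for bchL
LNAPDGGAATWQIDPAAQLGVNRGMSLSATEQTGRAICFFYADDDPLARIDYSTLNGKVDKTLTILLTGEIIEMQVRGDRSEEKGHEDEMAAVFQGCMAEGPIFKGTREGFNITRKLLGPDSVILLQDEAPDENEKNEAIIKFKEQIRLYAPLAVEQLKD
>SYNPGC028|bchM synthetic reference protein for bchM
ETRSWDKAQNRVNFKNPKLFGRQPWHGLGMMLQLAILLIPSIKVLENIHRNAAKKQGNLPVLVEFIVQLLGGGAEEDLEDLSELERSDDANSDFKEQLALVMATIGHYGTTESKVEGKAPNEVAIRDYYNELCIQLAPDADKARVAIRNIVGSFRAHKIPRRFIYFLPERKHWQ
>SYNPGC029|lhaA synthetic reference protein for lhaA
TCIKEHGHSDQPSIDLEFNEQGAILLTLNVTPAWDSWDDRLLLMIGAGALTNVLEHAAQYMADGCLIVIINLYAKLLVLMQPHFKGSTYRAYDNAQEFPAAPKFGMAERTKGDAGQSEDSYTSQHETVRAGAANAIIKKIAIFEKNLNVEIGCEHKPAFGHVPHDIVKPI
>SYNPGC030|puhA synthetic reference protein for puhA
YRTIIKQDSPLPPFETLNQVKFVPMVNLQPRRSTLDLPEFKPIDGRIGGVRPVQGGRVAGEKAAFIAANKIERMDKWNFAVLERLESQKGIASEEVTFNPEFVDQQDQLQSLPHGMAFPLAPPK
>SYNPGC031|puhB synthetic reference protein for puhB
HFMEPSWEGRVITAPNSGWKLSVEKSSDRMKLATGTKPIQADVKTFLSDEMMFLAADLYLQGCKWESSGDLVKLFRTKVAQEYFQTTAPEYRLMINAAAP
>SYNPGC032|puhC synthetic reference protein for puhC
DSDVWQRHIEIKFASRSGYLLDLSKGLLVTKLEDKYAPHGTKKLKVNPGLKPAKLAFLNAAVQSIDVIKGTAEELFLAVVLEIDSMYFLVSSVVPRIFLICGESSEDTGKIELLYRRKPAKCAPFLKLINLLIVVEDAKSQLRILRGPKPRDKSKEERIVA
>SYNPGC033|acsF synthetic reference protein for acsF
SSSKAIRVIDERELLDTLVSVIEGHKRSELTVASKAIFNVLPVITDEMALANEHSQAVPSEATVKKKCAAVRKPGTMAQPLTGNEDVKELSDVASGENEAAYSILNGAQESTKDIIGEVCKVNLIKSDPQVHYGVNHTKRMVYKIVENYVLSSRQILNQKVNEPF
>SYNPGC034|puhE synthetic reference protein for puhE
KPMHSIFLPGALSRMYRSTGIEVSVTKAWPGQGNFCSGLQTEILSKLLRISMVIKAERSAKPSIVSGVTVTLQGRVPSGSKLPNESQSQDIVVAESFDLYKQAQETHVDGESKLEVEVVGVLMQKSELPRPFERKNIEKFVFIKQVAEVSQITMVEGAGFANSRKPSTYVGNSLKDE
>SYNPGC035|cycA synthetic reference protein for cycA
ASDAYFRHPSKQKIAGAIPRKGAGLNPWNLVVGISKVLGSILPRAMTLDLLIPVVRKIDHSENVLGFFLENRITKITVGLKRKPELDTPRSTYVNMAFKTVRRPSKFPAKLSQPRIIEDGPKEKEVYMNPDIPAVGSSDINRKMSNFEYVIKSGSVNEGSWKAVIASLSEKGLQK
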