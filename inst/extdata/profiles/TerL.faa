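>TerL_fam1
KRLYASIIEFGGDRTISSSRTKNEPVMCARVVGEASFAAVSNLATGGMEAFIICYELFEGLHMGSEDAGE
VVEIGQEAWDICNCGAKQGKCVKELGGAADPLSSDKDECMTKLRAESLFATSACQSINQDVRTTIKDRAG
GARPIIACKSKEFIKGVSFDVARLFCMEQTVETFDEIGHIETQPLDSEDPKDKNAYPNSNLKRFLNRELM
ISASKSGQLIGVGGYLTIRARKRESKHLHNAPRYVCGVSIPKEPDGGLEEASAEVTIRDKKVSGSNKAAS
GDRPKVLTAERYIGSIHGDSVKIESLYFRDPLIAETNACHRTEAYKFDNSHGLGKALPSLTNGPADSNAL
NSMNVWTLLLAIGHIKSWSDAHGMGGCTDIQIVTLIEPEQERSRMEYSIEVDLDKVTPDDGEQSAVKDPG
YIEWCSAFTRKKSLHPNQVSTAALQVLGVLVVTRFYPYQDVTASISRNLMEVPIANVVVQQCILYPMIMK
FRASTYLRMPWNKTDLIAIGEGIQPAAGDTSLGTANESKPGNALGIENDRHGQGEGDVIDIGTLLFLQQI
LTTSGRLPDLCYAGDSFIQTQSDKRAAQKYTTSEARPVDI
>TerL_fam2
KRPVGQIIEFGGSRTISSYRAKSEAVKCAVVVRTFTFACVFNPAGGHMEAFIACYELFIGLHMGDEDYGE
SVVIGNEAWDLLNLGSGAGKCVKELGGAADILQSDKAECYTKLRDEPLFALSDDEYIIQDVRTTIKDRLG
GARPIILCKSVKFKKGVSFDVARLSCMEQTVLCEVEIQQIEGNPDDSLRPKDKNAYLNSNIKRFLNSNTL
IKASKSGPKAGVGGYLLIRAGNRESPTLHNAPRWVCGVTSSKEPDDGIEEHSPESTIRDKKVTGSNKSFS
IDRPKVLSAYRYIGSTHTLSVKIASLQFRDLAGAETNGCHRVEAYKFDNSHGKGYASPSITLGPVDSNAL
TSMNVVDLQLAIDHKDSWSKVTPMGGRNDEQIVDLEEPEQNRRCMEPSREYDLDKVTPDDGEESAVIDPG
EIDWFFWFTRRLSLHPLQFQFAALQVNLYLVVTRFAPDQIVFASNSLNLMEYAIANVSVGQCQLYPVTMK
FRAVTYLINPRNKTDDIAIGEPIMPVAGDTSYGTMGEPSLNNALGIENDLHGQFEGDVIDICLLLFLQVI
YTTSTTSEVLCAPGDSFIQGQSDKVAADKYTHDEARPLGG
>TerL_fam3
KRPVGQIIEFGKDRTISRSLALSHPFMCASVVLEAMFATVSNLATDHLETFIICYELFEGLHMGSEDYGE
WVPIGEEAWDILNCGAAAGKAVKVSGCAAQPLESDKALCHTKLRDETLFAGSSPAYVIQDVRTEIKEFLG
GARQIILCKLVEFIKGVSFPVARLSCMEVTVLCASEIGQIETQPLDSLRGSDKNCYPNSNICRFLVRNTL
VSASKSGFKIGLGGYLLDRAGKRESPGLHNALRWVCGVAIPKSPEGGIEEHSAISTIRDKKVSGSNWSFT
GDRPLVLRALTYIGSAHVDSVKICSLLFRDALIAETNGQQRVEARKLDNSHGKGKALASLTNGPVDSNAL
NSMNQVDLLLAIRHNSSWGEVNPMEGYTDIQIVDLIEPRQEKECMEYSRTYCLDKVTPYDGQVSLVKAID
YISGCFWFIRRLSLHPNQEETAQLQCLGVLVDTRFAMYNDVFAQINLGLGEYDIANVVVGNTILKPVIMK
FRASAYLIMPWNKTDHIAYGEAIVPAAGDTSYLTMGESDPLNALGIENSRHGQLTGTVIDIGTLLFLQQI
LTTSTRLPDLCAEGDSFIQTETDLTAAQKYIHLEARPLGI
>TerL_fam4
KSPVGQIIEFGGDRTISSSRAKGEPVMCARVHRGAMFATMSNLAGGHMIAFILCYKLFEHLHMNQEDYWA
WVVIGREAWDILNCGGGAGHKVYELGGAAQPLESDKATCMQKLRDETLFFTSSFEYNIQDKTTDIKDRLG
GARPIILCKSVEFIKGVSFDVADLSCMEQTVLCEFETGQILTQYLDSPRLKDKNAYPDPNEKRFLNRALL
ISASKSGFAIGVGGYLLIRADKRESPHLHNAPREPCGVMAPKEGNGGIERHSAKIFIRCKRVSGLNKSKS
ILRPKVVAAYRYIGSTHGDSVKIASLLGRDLLIHETNGCHRVEAYKFDNSHGKGDVQPSPFIGPVDSNAL
ESMNVVDLLLAIRHISSWEKVTPMGGCTDIQIVSLIEPNQERSCREYSREYDLDKVDPDDGEVRNVNDPG
YIEWCFWFERRLNLHPNQIDVAALQVLEVLVVFRFAPYQDVFASISLNLMGGPARNVVVRTCILPPVIMK
FRASTYLAMAWNKTDLIAIGLANEPAAGDRSYGTSGESEPLLALGIINDPRGQGEGDVDDIGTLLFLQQI
LTTSTRLPDLTAPGDSFIQTQSDRRAAQKAGHTEAAPLGN
>TerL_fam5
GKPQGQIIEFGGDRTASSSSAKSVPVMNARVVAEAMFATVSNLAGGHTEAFIILYELFEGLAMGSELYGE
TVYIGDEAWDIENCGAGAGKCVKEKGYAADPLESDKAECMTKLRDETLFATSSDEYIIIDVRTTIKDMLG
LARPIILCKSVEFEKGVEFDVARLSGMEQVVLCEVEEGQIETQPLDSPKPKDKVAYSVGNITRFLNRTLL
ISASKSGFKIGVGGYLLIRAAKSPSPHLHGATRPVCGVMIPKENDGGQEEHSAEKSIRDKKVSGSLKSFS
DDRPKALRAYGYDGSTHGDSVKIASLVFRDLLIAEENGCHRVEAYDFDNSPGKGKALPSLTNGPVDSEAL
NSMNVVDLYLAIRVIASLSKVTAMGGCTDIQIVMLIEPFHELSCMEYSKEYDLAKVRADDGGVNAVKDPG
FIEGPFWFTRRLSLGPNQIETAMLLVLGVLVVTREAPYQDVFAKINSGLMEYPIANVVVGQCILYPQIMK
SRASTYLAMPWIKTDSFAITNAEQPAAGDYSYGTMGESDPLNALGIENDRHGQGETDVIDIGTESFLQQI
LTTSTRLADLCAPGTSFIQTQKQCRAAQKLTSDEARPLGE
>TerL_fam6
KRPVAQIIEFGKDGTISSSRAKSKEVGCAKVVRELMFATVSRLAGGHMWAFIPCYELPEGLHMGSGDYGI
WVVIGNEAWDILPCGAGFFKCVKELGGAADPLESDKAEGMTKLRDETLFAKSSDEYIYQDDRNARKDRLG
GARPIILCKSVEFIHGVSFDVARLSCMEPTVLVERKEGQIEVQTLMSPRPKQHNFYPNSNIKRFLNRNLP
ISASKHIFKILVGGYLLIRAGKTESNHLHNAPRWICGVMIHKSKDGGIEEHSAEPTFRDKKVQASTKSFS
IDNPKVLRAQRYEGSTHLDSVKIASKNFRDLLITETNGCHDVEAYKTPVSHGKGKALPSLTNGPVSSPAL
NYMNVVDCLLAIRHISSWSKDTPMGGCTDIQIVDLIEPEQERSCMEYSRELDADKATIDNGPVSAVKDPG
YRMWNFWSTRRLSLHSNQIETAATQVLGRFVVTRFAVYQDVFASISLNLLEKPIANVVVGWCILYPVIMP
FDASTYIAKPWNPTDLIAISEAIQPAAGDQSGGIMNESDPSNALGIENDEIAQGEGDVIKIGTLLFLQQI
LTESSRLPDLCAPGKSGIQTQGNKRAANKYTHLEADPHGI
>TerL_var1
KRLYASISEFGGDRTISSSRTKNEPVMCARVLGEASFAAVSNLATGGKEAFIICYELFEGKHMGSEDAGE
VVEIGQGAWDICNCGAKQGKCVKELGGAADPLSSDKDECMTKLRAESLFATSACQSINQDVRTTIKDRAG
GAMDIIAQKSKEFIKGVSFDVARLFCMEQTVETFDEIGHIETEPLDSEDPKDKNAYPNSNLKRFLNRELM
ISASKSGQAIGQGGYLTIRARKRESKHLHNAARYVCGVSIPKEPDGGLYEASAEVTIRYAKVSGSNKAAS
GDRPKVLTAERYIGSVHGDSVKIESLYFRDPLIAETNACHRTEAYKFDFSHGLGKALPSLTNGPADSNAL
NSMNVWTLLLAIGHIKSRSDAHGMGGCTDIQIVTLLEPEQERSKMESSIEVDLDKVTPDEGEQSAVKDPG
YIEWCSAFTGKKSLHPNQVSTAALQVLGVLVVTGFYPVQDVTASISRILMEVPIANVRVQDCILYPMIMK
FRHSTYLRMPWNKTDLIAIGEGIQPQAGDTSLGTANESKPGNALGIENDRHGQGEGEVIDIGTLLFLQQI
LTTSGRLPDLCYAGDSFIQTQSDKRAAQKYTTSEARPVDI
>TerL_var2
KRPVGQIIEFGGSRTISSYRAKPGQVKCAVVVRTFTFACVFNPAGGHMEAFIACYELFIGLHMGDEDYGE
SVVIGNEAWDKLNLGSGAGKCVKELGGAADILQQDKAECYTKLRDEPLFALSNDEYIIQDVRTTIKDRLG
GARPIILCKSVKFKKGVYFDVARLSCMEQTVLCEVEIQQIEGNPDDSLRPKDKNAYLNSNIKRFLNSNFL
IKASKSGPKAGVGGYLLIPAGNRESPTLHNAPRWVCGVTSSKEPDDGAEEHSPEETIRDKTVTGSNKSFS
LDRPKVLSAYRYIGSTHTLSVKIASLQFRDLAGAETNGCHFVEAYKFDNSHGKGYASPSITLGPVDSNAL
TSMNVVDLQLAIDHKDSWSKVTPMGGRNDETIVDLEEPEQNLRCMEPSREYALDKVTPDDGEESAPIDPG
EIDWFFWFTRRLDLHPLQFQFAALQVNLYLVVTRFAPDQIVFASNSLNLMEYAYANVSVGQCQLYPVTMK
FRARTYLINPDNKTDDIAIGKPIMPVAGDTSYGTMGEPSLNNALGIENDLHGHFEGDFIDICLSLFLQVI
YTTGQTSEVKCAPGDSFIQGQSDKVAADKYTHDEARPLGG
>TerL_var3
KGPVGQIIEFGKDRGISRSLALSHPFMCASVVLEAMFRTVSNLATDHLEIFIISYELFEGLHMGIEDYGE
WVPIGEEAWDLGNCGAAAGKAVKVSGCAAQPLESGKALCHTKLRDETLFDGSSPAYVIQSVRTWEKEFLG
GARAIILCKLVLFIKGVSFPVARLSCMEVTVLCASEIGQIETQPEDSLRGSGKNCYPNSNICRFLVRNTL
VSASKSGFKIGLGGYLLDRAGKRESPGLHNALRWVCGVQIPKSPEGGIEEHSAISTIRDKKVSGSNWSFT
GDRPLVPRALTYIGSAHVDSVKICSLLFRDALITETNGQQRVEARKLDNSHGALKALASLTNGPVDSNAL
NSMNQVDLLLAIRHNSSWGEVNPMEGYTDIQIVDLIEPRIEKECMEYSKQYCLDKVTPYDGQVSLVKAID
YISGCFWFIRRLSIHPNQEETAKLQCLTVLVDTRFAMYNDVFAQINLGLGEYDAANLVVGNTILKPVIMK
TRASLYLIMPWNKTDHIAYGEAIVPAAGDTSYLTMGESDPLNALGIENSRHGQLTGTVIDIVTLLFLQQI
LTTSTRLPDLCAEGDSFIQTETDLTAAQKYIHKEADPLGI
>TerL_var4
KSPVGQIIEFGGDRFLSSSRAKGEPVMCARVHRGAMFATMSRLAGGHMIAFILCYKLFEHLHMNQEDYWA
WVVIGREAWDILNCGGGAGHKVYELGGAAQPLESDKATCMQKLPDETHFFTSSFEYNIQDKTTDIKDRLG
GARPIILCKSVEFIKGVSFDVADLSGMEQTVLCEFETGQILTQYLDSPRLKDKNAYPDPNEKRFLNRALL
ISASKSGFAIYVWGYLLIRADKRESPHKHNAPREPDGVMAVKEGNGYIERHSAKIKIRAKRVSGLNKSKS
ILRPKVVAAYRYIGSTHGASVKIASLLGRDLLIHETNGLHRVEAYKFDNSHGKGDVQPKPFIGMVDSNAL
ESMNVVDLLLAIRHISSWEKVTPMGGCTDIQIVSLIEPNDERSCREYSREYDLDKVPPDDGEVRNVNDPG
YIEWCFWFERRLNLHPNQIDVAALQVLEVLVVFRFAPYQDVFASISLNLMGGPARNVVVRTCILPPVRMK
FRASTYLAMAWNKTDLIAILLALEPAAGDRSYNSSGESEPLLALGIINDQFGQGEGDVDDIGTLLFLQQI
LTTSTRLPDLTAPGDSFIQTRSDRRAAQKAGHTEAAPLGN
>TerL_var5
GKPQGQIIEFGTDRTASSSSAKSVPVMNARVVAEAMFALVSNLANGHTEAFIILYELFEGLAMGSELYGE
TVYIGDEAWDIENSRAGAGGCVKEKGYALDPLESDKAECMTKLEDECLFATSSDEYIIIDVRTTIKDMLG
LARPIILCKSVEFEKGVEFDVMPLMGMEQVVLCEVEEGQIETQPLDDPKPKQKVAYSVGNITAFLNRTLL
ISASKSGFKIGVGGYLLIRAANSPSPHLHGATRPVCAVMIPKENRGGQSEHSAEKSIRDKKVSGSLKSFS
DDRPKALRAYGYDGSTHGDSVKIASLVFRDLLIAEENGCHRVEAYDFDNSPGKGKALPSLTNEPVDSEAL
NSMNVVDLYLAIRVIASLSKVTAMGGCTDIQDVMLIEPFHELSIMEYSKEYDLAKVRADDGGVNAVKDPG
FILGPFWFTRRLSLGPNRVETAMLLVLGVLEVTREAPYQDVFAKINSGLMEYPIRNVVVGQCILYPQIMK
SRASTNLAMPWIKTDSFAITNAEQNAAGDYSYGTMGERDPLNALGIENDRHGQGETDVIDIGTESFKQQI
LTTSTRLADLCAPGTSFIQTQKQCRAAQKLTFDEARPLVE
>TerL_var6
LRPVAQIIEFGKDGTISSSRAKSKEVGCAIAVRELMFATVSRLAGGHSWAFIPCYELPEGLHMGSGDYGI
WVVIGNEAWDLLPCGAGFFKCVKELGGAADPLESDQAEGMTKLRDETLFAKSSDEYIYQDDRNARKSRLG
GARYIILCKSVEFIHGVSFDVARLSCMEPTVLVEPKLGQIEVQTLMSPRPKQENFYPNSNIIRFLRRNLP
ISASKHIFKILVGGYLLIRAGKTESNHLHNAPRWICGVMIHKSKDGTIEKHSAEPTFRDKKVQASTKSFS
IDNPKVLRALRYEGSTHLDSVKIASKLFRDLLITETNGCHDVEAYKTPVSHGSGKALPSLTNGPVSSPAL
NYMNVVDCLLAIRHISSWSKDTPMGGCTDIQIVDLIEPEQERSCKEYSRELRADKGTIDNGPVSFVKDPG
YRMWNFASTRRLSLFSNQIMTAATQVLGRFVVTRFAVYQDVFASISLNLLEKPIANVVVGWCILYPVIMP
FDASAYIAKPWNPTDLIAISEAIQPAALDQSGRIMNESDPSNALGIENDEIAQGEGDVIKIGTLLFLQQI
LTESSRLPDLCAPGKGGIQTQGNKRAARKYTHLEADPHGI
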