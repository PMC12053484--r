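>UGP_018
PSITNNASPQWYSVSSTFDPILLTCDFAGDDKQRGAHVHCSTLYYYGFPGQALPAGKTQEYGMFILPNTP
LYKLGIIYATLATIKKFLNIMLGGIILSPPLGKEGLVADFNNAKFGLLWLLIEESVQKDCTPNAWKLDRK
ANVDDSAKRTPRSDIDTCGRSTKPGLPSDQQVESGLIKEVLFVYLQSGIQCAPGTYNLFQRLETFGFPFL
QDQFNPLNQGLDFIPHNIGFSDPADQNFGQFTNGSNNNPSMEYMTAIFRPVSGGRLATRGCLPMVEKTVI
RTWPLAADLKVKPSILLPMEVGGKKNPLSLANELLSRFALADADVGGGIIAGGSLTTMPDAPPGLVRAVV
GSTTDFEFAMVRLCKKGHTCVMDKIPENTQELTVEISQGQDYGGEIVMGFGGSTAMEADLRVHGQRYFGQ
DQLKNAGDSDQWLFPRFDAKPTAYVIGTVAAQEQWEEPEPMNHIKVDPMSFKNLIIEFGLGIHGLVHYYE
RIHFSVILIPDGLIGYGLKYLHKDYDRICFDESAAGALTKRAKSFKQKKEKLREVMQNKALEGVGLMTYD
GLTFDGEKCNGCIKASVVQYDVFATELPLAEHWPIRTNKVLYSSLTPGRVSCPNYEQVQKGPQVGDEVVQ
AAALHLSAALLFVHVDDHKQSGDEEGIDRADDKIHSNKQDDSYPQLKEGLNHFTAQKSNKLVRGLSMKDT
AEVDNPVRLLVLVEKKALDPLWAYVDNDSKGVFETSTEAYIAEAVLFKTK
>UGP_092
KRPVGQIIEFGGDRTISSSRAKSEPVMCARVVREAMFATVSNLAGGHMEAFIICYELFEGLHMGSEDYGE
WVVIGNEAWDILNCGAGAGKCVKELGGAADPLESDKAECMTKLRDETLFATSSDEYIIQDVRTTIKDRLG
GARPIILCKSVEFIKGVSFDVARLSCMEQTVLCEVEIGQIETQPLDSPRPKDKNAYPNSNIKRFLNRNLL
ISASKSGFKIGVGGYLLIRAGKRESPHLHNAPRWVCGVMIPKEPDGGIEEHSAESTIRDKKVSGSNKSFS
IDRPKVLRAYRYIGSTHGDSVKIASLLFRDLLIAETNGCHRVEAYKFDNSHGKGKALPSLTNGPVDSNAL
NSMNVVDLLLAIRHISSWSKVTPMGGCTDIQIVDLIEPEQERSCMEYSREYDLDKVTPDDGEVSAVKDPG
YIEWCFWFTRRLSLHPNQIETAALQVLGVLVVTRFAPYQDVFASISLNLMEYPIANVVVGQCILYPVIMK
FRASTYLAMPWNKTDLIAIGEAIQPAAGDTSYGTMGESDPLNALGIENDRHGQGEGDVIDIGTLLFLQQI
LTTSTRLPDLCAPGDSFIQTQSDKRAAQKYTHDEARPLGI
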