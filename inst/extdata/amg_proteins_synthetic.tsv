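symbol	protein
focA	MKLFDTVSGAVKNLGEQALHPMTMFATSVLAGAFIGLGGLFALTVNTGLGWLGALVFPVGFCMVILTGSELFTGNTMILPMAALRGKVGWGQMLRNWGIVYVGNLIGALLVAYLMVSSGLFDATSGVVGHKIVAIAEAKTHHSFAEAFFRGILCNWLVCLAVWMAMGAESVSKIIAIWFPIMAFVASGFEHSIANMFMIPMGIFIRDFAAPEFWTAIGVAPEDFSHLNVVHFITANLIPVTIGNIVGGGVLVGLTYWVIYLRGDSHH
nirA	MSDLKNEFKEGIASLRGSVADGLNDPVTGSLSEDDLKFLKFHGSYQQDNRDNRVKGQEKDYQFMLRTRLPGGVITPKQWLALDDLSDQYANGTLRLTTRQTFQLHGVLKKDLKTVMGTIIRNMGSTLGACGDLNRNVMAPAAPYVRKDYLFAQQLADNISALLTPQTGAYYEIWVDGEKAISAEEAPEVKAARPYNGNGHDFSDRNEPIYGTHYLPRKFKIAITVPPHNDVDVFTNDIGLIAIVENGELVGFNVSVGGGMGRTHGNEETFARLADPLGYVDKEDILDVVKAIVTTQRDYGNRSDRKNARMKYLIHDWGVEKFRAEVEKRLGQKLEPARPYHFESRGDRFGWVKGADNNWHLTLFIENGRIKDEPDYPLKTGLREIAKVHKGEFRLTANQNLIIAGVPESQKAKIEALLAEYGLTDFSAHSTRAYSMACVALPTCGLAMAEAERYLPSFVDKIEAILEKHGLQDEHIVMRVTGCPNGCARPYMAELGFVGDGPNSYQLWLGGTPNQTRLAQPYKERLAIHDLEKVLEPIFVYWKRKRQEGESFGDFTNRVGFDAIREFVDKYSPATIKA
nirK	MSKTLSRRQFLGASAATAALAATSFKAQAAGHHLHGDDSKIAHPQGLKALPLVTAELTAPPFVRSHEQVATSGPEINGQLIRYDLHVMEKEVQLAPGKSTQAWTFGGTVPGPVLRGKEGDTIRVTLKNELPEHTTVHWHGLRIDNAMDGVAGVTQDAVMPGESFTYEFTARQAGTYMYHSHVDSVKQLAMGLYGAFIVDPKQPRAYKYDRDYTLMLSDWWHESTDSIFRNLKKQSDWYAIPKGSVRPLRNMMSEMGLDAALHKRTLWNQMRMDPTDIADVTGATYTYLVNGHGPLDNWTGLFKPGEKVLLRIINAGAMDHPMHLHGHFFQVVATDGRPVAGAIKRDTVMVAPGETVTALLVADALGEWAFHCHLLYHMEMGMMRVVRYAG
norB	MGNFWAQRLLMTYGVLLAILFGVLGVTGMEVYGRGQTAEWFSSMSYIHSAHFILGMFGWGTLFMAAVMYYLVPRVSQTELYSERLAAFQFWGWNAGGLLAAISLLIGHQSGVMWTQLPTFIQPLLVVGLLLVFFNLMKTIAARNEPTISPVYFIMAGLFWLGILYLGAVHNVFDLSIQHHMFFQAGHAHLAFLGAFGMLALAMGVYYLRLITGQALYSEKLGKLSFWLINVGLVLMTFALLASGILQGLMWLEYDSFGSLAIQFMETVMFARNAGDVLFLVGGLAIAYNFLQTLRGRTAVASA
amoC	MSAATSMDPLKVAWDAFGRDAATTKAILGGLAAFVAFGLSYHIFMWGTGHDSFWEGFYHAHHVLIAPAHVAMLVGGLLPTVLTAFGAPLLPRAWTFLGRLRNTWFEPVVAIVFVLGLVSFWWGWSHYMYAMDMVPGAFAHDHSLMLSGADNPALMGSFHMHTVLFGALFPMFMMATGYHAWHVIRNREADLSPKAELVTLGAFLAAGAATFASWSHYPINFVGAESWIDGIGRVFSHQELIAFGEAGFWRLIHAIASTYFFAGLLTLGLSAWKVLRGQEPTLAGAHAH
glnK	MKLITAIIKPFKLDEVREALSEIGIQGLTVTEVKGFGRQKGHTELYRGAEYVVDFLPKVKLEIAVPDDIVDQCVDAIINAAHTGKIGDGKIFVFDVARVIRIRTGEEDDAAI
amtB	MSPNMAWLLVCTALVLFMTLPGLALFYGGLVRSKNVLSVLMQCFAIACLVSILWVVYGYSLAFGEGNSFIGGLDKLFLNGVTVDSLSGTIPEILFVAFQMTFAIITPALISGAFAERMKFSAMLVFITLWSLFVYAPVAHWVWGGGWLADLGVLDFAGGTVVHINAGVAGLVGAYLLGKRVGFGKEAMAPHNLGLTMIGAALLWVGWFGFNAGSALAANGSAANAFMVTNTSAAAGGLTWMLIEWLHRGKPSVLGAATGAVAGLVAITPAAGFVGVGGALVIGLVAGVVCNLAVGLKSKLGLDDSLDVFGVHGVGGIVGAILTGVFATTSVNSVGADGLFYGGGLTQLGIQALGVAVSWVLAAGGTFVILKIIDLTIGLRVSEEEEREGLDVTSHGESAYHS
ompL	MKKTLLATAVLASFAGMAQAADVTLYGRAHVSLDYLDNGADSEVTQLASNSSRLGFKGHEDLGGGLKAGFQLESGINLGDGATAGDTFFARNAYVGLSGAFGTVLAGRQYTPMFMLLGKIDPFSAGTAGDMKNLFTVHNGRESNAVRYDSPNFSGFSASVSYGFGEQAGSLSADRAFSAGLSYENGGFFAAFAYDQQNGSSATADRSDFTLGGSYDFGVAKVFGLFSQVQHDAAGNKNNGYELGAAIPVGAGEILASYQYTDLDSNAADDSAHQFALGYVYNLSKRTNVYAVGTYQHASGTDADSTMAVVGMRHRF
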