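>TGFBI synthetic stand-in sequence, 683 aa; embeds LAPVYQKLLER at 670-680 (K676); not the UniProt Q15582 record
QGCCYKHQASMVGRIWVPVQSSATCLCRLTYIVLPKCQDGFPRDIWEPEVYKYTNYYHTA
ALHEWRGENTHMQKCGPCLNGHQKYVQQTWDKVCAYAAWAPRHAIHIMVPDRSLQQMGWR
IPCGHLSGRHIIHLWHIRLVSCEQAVYNAARILYQHHMFCRVYWATIFHLRASQLTCSAW
RHEAHHMYKMYASVKFGCFSRYECFLHYMNSGRICVYGHRFTGNMIGMGPKEHNEPADQH
FLLVRDQNALIMCYRATFPEYGYYFTRAITVEFNIRHEPEVFSIEKLAEAIMTDGLVWGK
VTISQSRFNNGFCNESRGYETVLARMEEWWRVFDAYPRNQYIHHFQTPFAMKYMWAICTA
LYRMAIYERCVEHCIMLSLCCFKQEIWEEMCDCKLIDQIKWQDFHNVSARCSCLEHKLEH
HTYHAYSLPNKIEFGASDHPWKCHQDNDKTTHAPHKQHPILRLAACHCHYHMGKDPIGFF
HDPVRYSVPVAAILSRFSIYECYGWWKIPPHWTAQVSQICRVFQPHYQENIGHSKVQCDA
RHSDDVFMTNERDQMVVDSFQKIDIVGETMYGNDAKADDLQNVKSTMPSNQKVQQSIRFV
ILLTPVHTILKSNSQAFRNVNLERLEVEWSHQPKVPLMWFGKLTSPMGPIGQTRGLMECA
NVNYKCCERLAPVYQKLLERMTL
>NFKB2 synthetic stand-in sequence, 900 aa; embeds YGCEGPSHGGLPGASSEKGR at 55-74 (K72) and GHTPLDLTCSTKVK at 730-743 (K741); not the UniProt Q00653 record
ANPEHWTGQWGSRQFQVPNFKIFEWYWIPFWQWKDMYFAVVVQHLDEKGAICHKYGCEGP
SHGGLPGASSEKGRTQCGGACKSHGQHKIIFHCQDWPYNKWPWDIEWSIVRNLGGTRGIL
TGMQCWTERLYPFARMTHSPLRGMMDQVNRNLHDGELRYHIHECRQNYMLCFFLLRVTSQ
TRITSSQEAMVKQGNACCKNYVWYGQLTKNQCPTWQVMEKAVNLWEWTSSNLRFDVIWDF
PYWNVRDEEIFTCGFRHWVGHGAAMNFAERIENGPEHHLGPKHLYCGHLHACKCFDMWRI
SLPYTWMRITDYHIICCQEMYKMINEWVCNKWLGDSFQAVEIKAILEILRITQLYPVYPL
QAKSWFLDFYGFWHLTKCPLLSPVNAQHKDEMCTDMWYTAVRVQGEPHDMTLAQRQMLQY
HFTHTRDNMQHYAVWSCWKLLNVWWNEARCGEWVFMPQTTLRSYDQGTHFVQKTDTPHWL
FEKWQVYCMIQNMCKSHEAAFPDSNDDKGQWWLYTISAWKYDIWDSFWHCAHHKFWWLTM
YIPYGKGPLQYHTTRWPMTDNRQQTHQQQCDKHPVCEWFEYCFEKMTVTTMTSSHDAAKV
DGSCFKMHYTNYQHIWWRMAQITFEHANYPKYVYWLFRFWIPIHGFHWSYNRSFALWYPE
KSVGQVQKIDLNTIMDQIFRVDCWEWRTHLCSMRQHPWELKNMHTGARLILHGLAAFYSG
RDHNFYDMRGHTPLDLTCSTKVKNLNYDYLGVWNSGCFVFNLQGNAYNNGNFLCTVIHYH
MGHNWTNIFACYGHYGAASSNFLYMQPTCNICEFQYCDWNQTFAQIIMSVHATTCGEMYG
LPVSCAETNPAGPNPTTHTDPWNFECMNSVAFFLVIAHNEIEEDFMHENHDEQHIISYPL
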