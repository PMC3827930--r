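{
  "id": "SYN_LIP3",
  "sequence": "IAQPDHGIPMTQRVLGSDKAQWFPVSYKKPKHFEMVFSAVKKRFKDYVRYYKQRLSQMQCYQSKTRAQSKAKIQRWFDSRVTRSVRYTLIHESQWDCDYYEAKTQIYARWEAGTTWTMISKGGGFSMLPYPIDHGLLVLQVDWETFLPAKELPWYDMRLIWQTGHWHVAGQWMRVWRSVQVRLDIADYGFFAHDVLQVFLGGDDWYGESAGSMLAPHMWAHLLKKFWESSQHDMFPDKTKDLFFALHFQHFLDSIPWRYDFQGHKVAPSRAPWIWLVGIYFYIAYHGQRHIWQVHLKKHNASGFDGRPIDATQFWRKYGQMTPMYTYRFQSRFFYELQMAEVHYRVSFPQTFLRLGVPFASFSAMMQGQSFQKMKWKRWAMIQEFQPEFVLDDTWQHELEKSYTPWFSTDSGLAPWYIKVVWAKALMSVRRTPLLRQKVLVWGGLWSYHDIHTMMIRQHKSKSIDMTIQEHIPGHMTMKDRAHAAQGYLPDEYPMVQDFLKGIHSQSMEEDQLHSSEFKPKRIAVPHKWPSGGL",
  "gggf_start": 122,
  "gesag_start": 207,
  "ser": 209,
  "glu": 341,
  "his": 449,
  "cys": [60, 97],
  "note": "synthetic Lip3 stand-in; mature-chain numbering, precursor = mature + 15 (GGGF 137, GESAG 222)"
}
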