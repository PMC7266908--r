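"target","phantom_mass_g","s_gy_per_mbq_h","source"
"kidneys_both",310,0.000281132,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"kidney_single",155,0.000560266,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"red_marrow",1170,7.51235e-05,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",1,0.0855804,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",2,0.0428413,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",4.19,0.0204798,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",6,0.0143133,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",8,0.0107425,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",10,0.00859894,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",15,0.00573903,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",20,0.00430795,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",30,0.00287569,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",40,0.00215891,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",60,0.00144145,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",80,0.00108233,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",100,0.000866683,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",150,0.000578851,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",200,0.000434748,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",300,0.000290451,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",500,0.000174788,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",700,0.000125116,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
"sphere",1000,8.77949e-05,"synthetic: 177Lu energy-deposition arithmetic (0.1473 MeV/decay non-penetrating + mass-dependent photon fraction), ICRP-89-like masses; illustrative, not a vendor table"
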