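# Discrete wavelet filter tables (analysis/synthesis pairs) for the
# candidate mother wavelets.  Coefficients follow the standard published
# constructions (Daubechies extremal-phase, least-asymmetric symlets,
# coiflets, spline biorthogonal pairs), stored to full double precision.
# Regenerate by evaluating the standard constructions; do not edit by hand.
.wavelet_filter_table <- list(
  "haar" = list(
    family = "haar", vanishing_moments = 1L, orthogonal = TRUE,
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)
  ),
  "db5" = list(
    family = "daubechies", vanishing_moments = 5L, orthogonal = TRUE,
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274, 0.07757149384004572, -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.7243085284377729, 0.6038292697971896, 0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.6038292697971896, -0.7243085284377729, 0.13842814590132074, 0.24229488706638203, -0.032244869584638375, -0.07757149384004572, -0.006241490212798274, 0.012580751999081999, 0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729, 0.13842814590132074, -0.24229488706638203, -0.032244869584638375, 0.07757149384004572, -0.006241490212798274, -0.012580751999081999, 0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.006241490212798274, -0.07757149384004572, -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.7243085284377729, 0.6038292697971896, -0.16010239797419293)
  ),
  "db37" = list(
    family = "daubechies", vanishing_moments = 37L, orthogonal = TRUE,
    dec_lo = c(4.9066150649352034e-18, -1.1992803358528796e-16, 1.1890123875082528e-15, -5.243025691884206e-15, -4.518889607463727e-16, 1.1380528309214397e-13, -4.4216124098721056e-13, -2.0963631942348006e-13, 6.3349554409739135e-12, -1.3984157155376414e-11, -3.203398244123242e-11, 1.946164894082315e-10, -1.031411129096975e-10, -1.297205001469435e-09, 2.793974465953983e-09, 4.224485706362419e-09, -2.2521938367248057e-08, 5.3506575154614344e-09, 1.1090312322164394e-07, -1.5098853886715837e-07, -3.494948603445728e-07, 1.0021213992971776e-06, 4.854731396996412e-07, -4.3099415565970926e-06, 1.8499450031155903e-06, 1.3543277184167817e-05, -1.6391624961605832e-05, -3.09866292761993e-05, 7.055138782065466e-05, 4.336726125945695e-05, -0.00022089440324554938, 1.5344390231955034e-05, 0.0005490532773373631, -0.00032807884708801983, -0.0011114848653186302, 0.0012639342581174772, 0.0018168713438014236, -0.0033945232764083988, -0.0022480531870038246, 0.007387757452855584, 0.0015193057788333991, -0.013763981962894785, 0.0016904723834844238, 0.022618651544599473, -0.008833493890410233, -0.03352358406410097, 0.020972800592597547, 0.045807944151268334, -0.03825382947938425, -0.05925681563265897, 0.059567410871529954, 0.07504761994836018, -0.08233021190655741, -0.09660754061668439, 0.10178029683881418, 0.12992964695985376, -0.10845171382330178, -0.181962291778608, 0.08180602838721862, 0.2515232543602687, 0.01967150045235939, -0.29437591526266177, -0.24618042976108342, 0.13087896323302017, 0.4622075536616057, 0.5181670408556229, 0.36844097240030615, 0.18732633186206493, 0.0705848259771816, 0.01976228615387959, 0.0040241403682572865, 0.0005662418377066724, 4.942343750628132e-05, 2.0220608624983923e-06),
    dec_hi = c(-2.0220608624983923e-06, 4.942343750628132e-05, -0.0005662418377066724, 0.0040241403682572865, -0.01976228615387959, 0.0705848259771816, -0.18732633186206493, 0.36844097240030615, -0.5181670408556229, 0.4622075536616057, -0.13087896323302017, -0.24618042976108342, 0.29437591526266177, 0.01967150045235939, -0.2515232543602687, 0.08180602838721862, 0.181962291778608, -0.10845171382330178, -0.12992964695985376, 0.10178029683881418, 0.09660754061668439, -0.08233021190655741, -0.07504761994836018, 0.059567410871529954, 0.05925681563265897, -0.03825382947938425, -0.045807944151268334, 0.020972800592597547, 0.03352358406410097, -0.008833493890410233, -0.022618651544599473, 0.0016904723834844238, 0.013763981962894785, 0.0015193057788333991, -0.007387757452855584, -0.0022480531870038246, 0.0033945232764083988, 0.0018168713438014236, -0.0012639342581174772, -0.0011114848653186302, 0.00032807884708801983, 0.0005490532773373631, -1.5344390231955034e-05, -0.00022089440324554938, -4.336726125945695e-05, 7.055138782065466e-05, 3.09866292761993e-05, -1.6391624961605832e-05, -1.3543277184167817e-05, 1.8499450031155903e-06, 4.3099415565970926e-06, 4.854731396996412e-07, -1.0021213992971776e-06, -3.494948603445728e-07, 1.5098853886715837e-07, 1.1090312322164394e-07, -5.3506575154614344e-09, -2.2521938367248057e-08, -4.224485706362419e-09, 2.793974465953983e-09, 1.297205001469435e-09, -1.031411129096975e-10, -1.946164894082315e-10, -3.203398244123242e-11, 1.3984157155376414e-11, 6.3349554409739135e-12, 2.0963631942348006e-13, -4.4216124098721056e-13, -1.1380528309214397e-13, -4.518889607463727e-16, 5.243025691884206e-15, 1.1890123875082528e-15, 1.1992803358528796e-16, 4.9066150649352034e-18),
    rec_lo = c(2.0220608624983923e-06, 4.942343750628132e-05, 0.0005662418377066724, 0.0040241403682572865, 0.01976228615387959, 0.0705848259771816, 0.18732633186206493, 0.36844097240030615, 0.5181670408556229, 0.4622075536616057, 0.13087896323302017, -0.24618042976108342, -0.29437591526266177, 0.01967150045235939, 0.2515232543602687, 0.08180602838721862, -0.181962291778608, -0.10845171382330178, 0.12992964695985376, 0.10178029683881418, -0.09660754061668439, -0.08233021190655741, 0.07504761994836018, 0.059567410871529954, -0.05925681563265897, -0.03825382947938425, 0.045807944151268334, 0.020972800592597547, -0.03352358406410097, -0.008833493890410233, 0.022618651544599473, 0.0016904723834844238, -0.013763981962894785, 0.0015193057788333991, 0.007387757452855584, -0.0022480531870038246, -0.0033945232764083988, 0.0018168713438014236, 0.0012639342581174772, -0.0011114848653186302, -0.00032807884708801983, 0.0005490532773373631, 1.5344390231955034e-05, -0.00022089440324554938, 4.336726125945695e-05, 7.055138782065466e-05, -3.09866292761993e-05, -1.6391624961605832e-05, 1.3543277184167817e-05, 1.8499450031155903e-06, -4.3099415565970926e-06, 4.854731396996412e-07, 1.0021213992971776e-06, -3.494948603445728e-07, -1.5098853886715837e-07, 1.1090312322164394e-07, 5.3506575154614344e-09, -2.2521938367248057e-08, 4.224485706362419e-09, 2.793974465953983e-09, -1.297205001469435e-09, -1.031411129096975e-10, 1.946164894082315e-10, -3.203398244123242e-11, -1.3984157155376414e-11, 6.3349554409739135e-12, -2.0963631942348006e-13, -4.4216124098721056e-13, 1.1380528309214397e-13, -4.518889607463727e-16, -5.243025691884206e-15, 1.1890123875082528e-15, -1.1992803358528796e-16, 4.9066150649352034e-18),
    rec_hi = c(4.9066150649352034e-18, 1.1992803358528796e-16, 1.1890123875082528e-15, 5.243025691884206e-15, -4.518889607463727e-16, -1.1380528309214397e-13, -4.4216124098721056e-13, 2.0963631942348006e-13, 6.3349554409739135e-12, 1.3984157155376414e-11, -3.203398244123242e-11, -1.946164894082315e-10, -1.031411129096975e-10, 1.297205001469435e-09, 2.793974465953983e-09, -4.224485706362419e-09, -2.2521938367248057e-08, -5.3506575154614344e-09, 1.1090312322164394e-07, 1.5098853886715837e-07, -3.494948603445728e-07, -1.0021213992971776e-06, 4.854731396996412e-07, 4.3099415565970926e-06, 1.8499450031155903e-06, -1.3543277184167817e-05, -1.6391624961605832e-05, 3.09866292761993e-05, 7.055138782065466e-05, -4.336726125945695e-05, -0.00022089440324554938, -1.5344390231955034e-05, 0.0005490532773373631, 0.00032807884708801983, -0.0011114848653186302, -0.0012639342581174772, 0.0018168713438014236, 0.0033945232764083988, -0.0022480531870038246, -0.007387757452855584, 0.0015193057788333991, 0.013763981962894785, 0.0016904723834844238, -0.022618651544599473, -0.008833493890410233, 0.03352358406410097, 0.020972800592597547, -0.045807944151268334, -0.03825382947938425, 0.05925681563265897, 0.059567410871529954, -0.07504761994836018, -0.08233021190655741, 0.09660754061668439, 0.10178029683881418, -0.12992964695985376, -0.10845171382330178, 0.181962291778608, 0.08180602838721862, -0.2515232543602687, 0.01967150045235939, 0.29437591526266177, -0.24618042976108342, -0.13087896323302017, 0.4622075536616057, -0.5181670408556229, 0.36844097240030615, -0.18732633186206493, 0.0705848259771816, -0.01976228615387959, 0.0040241403682572865, -0.0005662418377066724, 4.942343750628132e-05, -2.0220608624983923e-06)
  ),
  "sym5" = list(
    family = "symlet", vanishing_moments = 5L, orthogonal = TRUE,
    dec_lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936, 0.7234076904024206, 0.6339789634582119, 0.01660210576452232, -0.17532808990845047, -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047, 0.01660210576452232, -0.6339789634582119, 0.7234076904024206, -0.1993975339773936, -0.039134249302383094, -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.01660210576452232, 0.6339789634582119, 0.7234076904024206, 0.1993975339773936, -0.039134249302383094, 0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936, 0.7234076904024206, -0.6339789634582119, 0.01660210576452232, 0.17532808990845047, -0.021101834024758855, -0.019538882735286728)
  ),
  "sym18" = list(
    family = "symlet", vanishing_moments = 18L, orthogonal = TRUE,
    dec_lo = c(2.6126125564836423e-06, 1.354915761832114e-06, -4.5246757874949856e-05, -1.4020992577726755e-05, 0.00039616840638254753, 7.021273459036268e-05, -0.002313871814506099, -0.00041152110923597756, 0.009502164390962365, 0.001642986397278216, -0.030325091089369604, -0.005077085160757053, 0.08421992997038655, 0.03399566710394736, -0.15993814866932407, -0.052029158983952786, 0.47396905989393956, 0.7536291401017928, 0.40148386057061813, -0.032480573290138676, -0.07379920729060717, 0.028529597039037808, 0.006277944554311694, -0.03171268473181454, -0.0032607442000749834, 0.015012356344250213, 0.001087784789595693, -0.005239789683026608, -0.00018877623940755607, 0.0014280863270832796, 4.741614518373667e-05, -0.0002658301102424104, -9.858816030140058e-06, 2.955743762093081e-05, 7.847298055831765e-07, -1.5131530692371587e-06),
    dec_hi = c(1.5131530692371587e-06, 7.847298055831765e-07, -2.955743762093081e-05, -9.858816030140058e-06, 0.0002658301102424104, 4.741614518373667e-05, -0.0014280863270832796, -0.00018877623940755607, 0.005239789683026608, 0.001087784789595693, -0.015012356344250213, -0.0032607442000749834, 0.03171268473181454, 0.006277944554311694, -0.028529597039037808, -0.07379920729060717, 0.032480573290138676, 0.40148386057061813, -0.7536291401017928, 0.47396905989393956, 0.052029158983952786, -0.15993814866932407, -0.03399566710394736, 0.08421992997038655, 0.005077085160757053, -0.030325091089369604, -0.001642986397278216, 0.009502164390962365, 0.00041152110923597756, -0.002313871814506099, -7.021273459036268e-05, 0.00039616840638254753, 1.4020992577726755e-05, -4.5246757874949856e-05, -1.354915761832114e-06, 2.6126125564836423e-06),
    rec_lo = c(-1.5131530692371587e-06, 7.847298055831765e-07, 2.955743762093081e-05, -9.858816030140058e-06, -0.0002658301102424104, 4.741614518373667e-05, 0.0014280863270832796, -0.00018877623940755607, -0.005239789683026608, 0.001087784789595693, 0.015012356344250213, -0.0032607442000749834, -0.03171268473181454, 0.006277944554311694, 0.028529597039037808, -0.07379920729060717, -0.032480573290138676, 0.40148386057061813, 0.7536291401017928, 0.47396905989393956, -0.052029158983952786, -0.15993814866932407, 0.03399566710394736, 0.08421992997038655, -0.005077085160757053, -0.030325091089369604, 0.001642986397278216, 0.009502164390962365, -0.00041152110923597756, -0.002313871814506099, 7.021273459036268e-05, 0.00039616840638254753, -1.4020992577726755e-05, -4.5246757874949856e-05, 1.354915761832114e-06, 2.6126125564836423e-06),
    rec_hi = c(2.6126125564836423e-06, -1.354915761832114e-06, -4.5246757874949856e-05, 1.4020992577726755e-05, 0.00039616840638254753, -7.021273459036268e-05, -0.002313871814506099, 0.00041152110923597756, 0.009502164390962365, -0.001642986397278216, -0.030325091089369604, 0.005077085160757053, 0.08421992997038655, -0.03399566710394736, -0.15993814866932407, 0.052029158983952786, 0.47396905989393956, -0.7536291401017928, 0.40148386057061813, 0.032480573290138676, -0.07379920729060717, -0.028529597039037808, 0.006277944554311694, 0.03171268473181454, -0.0032607442000749834, -0.015012356344250213, 0.001087784789595693, 0.005239789683026608, -0.00018877623940755607, -0.0014280863270832796, 4.741614518373667e-05, 0.0002658301102424104, -9.858816030140058e-06, -2.955743762093081e-05, 7.847298055831765e-07, 1.5131530692371587e-06)
  ),
  "coif5" = list(
    family = "coiflet", vanishing_moments = 5L, orthogonal = TRUE,
    dec_lo = c(-9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05, 0.00014035632812373243, 0.0003018579416682448, -0.0006375589261258812, -0.0016616273039298788, 0.0024315754425382886, 0.006761520220620417, -0.009159507338676163, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834, -0.10556315130733723, -0.06203775157498196, 0.4379823066591634, 0.7742936228603274, 0.42157126673075435, -0.052046670253554764, -0.09192158806008609, 0.028169744270532353, 0.023408322118927783, -0.010131584846900276, -0.00415931262757864, 0.0021782943778456947, 0.0003585777411617577, -0.000212081862067494),
    dec_hi = c(0.000212081862067494, 0.0003585777411617577, -0.0021782943778456947, -0.00415931262757864, 0.010131584846900276, 0.023408322118927783, -0.028169744270532353, -0.09192158806008609, 0.052046670253554764, 0.42157126673075435, -0.7742936228603274, 0.4379823066591634, 0.06203775157498196, -0.10556315130733723, -0.041287530472117834, 0.032674799467057355, 0.019758391600965465, -0.009159507338676163, -0.006761520220620417, 0.0024315754425382886, 0.0016616273039298788, -0.0006375589261258812, -0.0003018579416682448, 0.00014035632812373243, 4.12198619242655e-05, -2.1270221672515614e-05, -3.7007277113394796e-06, 2.0612203985788783e-06, 1.6237995172048338e-07, -9.604010112767894e-08),
    rec_lo = c(-0.000212081862067494, 0.0003585777411617577, 0.0021782943778456947, -0.00415931262757864, -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.09192158806008609, -0.052046670253554764, 0.42157126673075435, 0.7742936228603274, 0.4379823066591634, -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355, -0.019758391600965465, -0.009159507338676163, 0.006761520220620417, 0.0024315754425382886, -0.0016616273039298788, -0.0006375589261258812, 0.0003018579416682448, 0.00014035632812373243, -4.12198619242655e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06, -1.6237995172048338e-07, -9.604010112767894e-08),
    rec_hi = c(-9.604010112767894e-08, 1.6237995172048338e-07, 2.0612203985788783e-06, -3.7007277113394796e-06, -2.1270221672515614e-05, 4.12198619242655e-05, 0.00014035632812373243, -0.0003018579416682448, -0.0006375589261258812, 0.0016616273039298788, 0.0024315754425382886, -0.006761520220620417, -0.009159507338676163, 0.019758391600965465, 0.032674799467057355, -0.041287530472117834, -0.10556315130733723, 0.06203775157498196, 0.4379823066591634, -0.7742936228603274, 0.42157126673075435, 0.052046670253554764, -0.09192158806008609, -0.028169744270532353, 0.023408322118927783, 0.010131584846900276, -0.00415931262757864, -0.0021782943778456947, 0.0003585777411617577, 0.000212081862067494)
  ),
  "coif14" = list(
    family = "coiflet", vanishing_moments = 14L, orthogonal = TRUE,
    dec_lo = c(-6.972752077994577e-19, -9.112090547755774e-19, 4.000437986126701e-17, 5.286274517465632e-17, -1.1286067317116846e-15, -1.5093680534110733e-15, 2.087175435684504e-14, 2.827804378477004e-14, -2.845914016875714e-13, -3.9104860636051463e-13, 3.051235212860773e-12, 4.257417896733187e-12, -2.6789821104151334e-11, -3.801184928644451e-11, 1.9809120346710113e-10, 2.862848247030911e-10, -1.2590752100024664e-09, -1.8568684752939706e-09, 6.987387541011994e-09, 1.0538640451894265e-08, -3.427757286145719e-08, -5.300650696936342e-08, 1.5013413713144253e-07, 2.3876494051964654e-07, -5.919974641332918e-07, -9.71842353346463e-07, 2.1160757624955858e-06, 3.602893601306652e-06, -6.8957093978400805e-06, -1.2254515725465707e-05, 2.0583278936576757e-05, 3.849201590195014e-05, -5.65441840412094e-05, -0.00011221961943808774, 0.00014390413588042603, 0.0003043599006063343, -0.00034297286150624035, -0.0007668251488526076, 0.0007777201566101956, 0.0017856181989036103, -0.0017080538661070365, -0.003814524076580171, 0.0036793235019773754, 0.0074157782307655, -0.0077852024170722255, -0.013024088005389463, 0.016067283926065306, 0.020539499874530513, -0.03220185256406462, -0.02894925613194684, 0.063646203141354, 0.03633187623818003, -0.13372942834321538, -0.04047709315229175, 0.4473406567537405, 0.7470249379615077, 0.43828475995016103, -0.03474484970544801, -0.12513713600885462, 0.02660154627198806, 0.05596345341137636, -0.01784235415243864, -0.02579684377082798, 0.010430949170645139, 0.01114255210951469, -0.005281202836308561, -0.004323062280774556, 0.0022967107264584086, 0.0014661214569906416, -0.0008488083847885695, -0.00042463732869716845, 0.0002628623520649985, 0.00010248333219568599, -6.692604993754285e-05, -1.9995576397409376e-05, 1.3640357675528054e-05, 3.0247808186844957e-06, -2.1394639250579226e-06, -3.324658385771607e-07, 2.424279845810464e-07, 2.360235756379167e-08, -1.7662495148738494e-08, -8.118993462836169e-10, 6.212814528402405e-10),
    dec_hi = c(-6.212814528402405e-10, -8.118993462836169e-10, 1.7662495148738494e-08, 2.360235756379167e-08, -2.424279845810464e-07, -3.324658385771607e-07, 2.1394639250579226e-06, 3.0247808186844957e-06, -1.3640357675528054e-05, -1.9995576397409376e-05, 6.692604993754285e-05, 0.00010248333219568599, -0.0002628623520649985, -0.00042463732869716845, 0.0008488083847885695, 0.0014661214569906416, -0.0022967107264584086, -0.004323062280774556, 0.005281202836308561, 0.01114255210951469, -0.010430949170645139, -0.02579684377082798, 0.01784235415243864, 0.05596345341137636, -0.02660154627198806, -0.12513713600885462, 0.03474484970544801, 0.43828475995016103, -0.7470249379615077, 0.4473406567537405, 0.04047709315229175, -0.13372942834321538, -0.03633187623818003, 0.063646203141354, 0.02894925613194684, -0.03220185256406462, -0.020539499874530513, 0.016067283926065306, 0.013024088005389463, -0.0077852024170722255, -0.0074157782307655, 0.0036793235019773754, 0.003814524076580171, -0.0017080538661070365, -0.0017856181989036103, 0.0007777201566101956, 0.0007668251488526076, -0.00034297286150624035, -0.0003043599006063343, 0.00014390413588042603, 0.00011221961943808774, -5.65441840412094e-05, -3.849201590195014e-05, 2.0583278936576757e-05, 1.2254515725465707e-05, -6.8957093978400805e-06, -3.602893601306652e-06, 2.1160757624955858e-06, 9.71842353346463e-07, -5.919974641332918e-07, -2.3876494051964654e-07, 1.5013413713144253e-07, 5.300650696936342e-08, -3.427757286145719e-08, -1.0538640451894265e-08, 6.987387541011994e-09, 1.8568684752939706e-09, -1.2590752100024664e-09, -2.862848247030911e-10, 1.9809120346710113e-10, 3.801184928644451e-11, -2.6789821104151334e-11, -4.257417896733187e-12, 3.051235212860773e-12, 3.9104860636051463e-13, -2.845914016875714e-13, -2.827804378477004e-14, 2.087175435684504e-14, 1.5093680534110733e-15, -1.1286067317116846e-15, -5.286274517465632e-17, 4.000437986126701e-17, 9.112090547755774e-19, -6.972752077994577e-19),
    rec_lo = c(6.212814528402405e-10, -8.118993462836169e-10, -1.7662495148738494e-08, 2.360235756379167e-08, 2.424279845810464e-07, -3.324658385771607e-07, -2.1394639250579226e-06, 3.0247808186844957e-06, 1.3640357675528054e-05, -1.9995576397409376e-05, -6.692604993754285e-05, 0.00010248333219568599, 0.0002628623520649985, -0.00042463732869716845, -0.0008488083847885695, 0.0014661214569906416, 0.0022967107264584086, -0.004323062280774556, -0.005281202836308561, 0.01114255210951469, 0.010430949170645139, -0.02579684377082798, -0.01784235415243864, 0.05596345341137636, 0.02660154627198806, -0.12513713600885462, -0.03474484970544801, 0.43828475995016103, 0.7470249379615077, 0.4473406567537405, -0.04047709315229175, -0.13372942834321538, 0.03633187623818003, 0.063646203141354, -0.02894925613194684, -0.03220185256406462, 0.020539499874530513, 0.016067283926065306, -0.013024088005389463, -0.0077852024170722255, 0.0074157782307655, 0.0036793235019773754, -0.003814524076580171, -0.0017080538661070365, 0.0017856181989036103, 0.0007777201566101956, -0.0007668251488526076, -0.00034297286150624035, 0.0003043599006063343, 0.00014390413588042603, -0.00011221961943808774, -5.65441840412094e-05, 3.849201590195014e-05, 2.0583278936576757e-05, -1.2254515725465707e-05, -6.8957093978400805e-06, 3.602893601306652e-06, 2.1160757624955858e-06, -9.71842353346463e-07, -5.919974641332918e-07, 2.3876494051964654e-07, 1.5013413713144253e-07, -5.300650696936342e-08, -3.427757286145719e-08, 1.0538640451894265e-08, 6.987387541011994e-09, -1.8568684752939706e-09, -1.2590752100024664e-09, 2.862848247030911e-10, 1.9809120346710113e-10, -3.801184928644451e-11, -2.6789821104151334e-11, 4.257417896733187e-12, 3.051235212860773e-12, -3.9104860636051463e-13, -2.845914016875714e-13, 2.827804378477004e-14, 2.087175435684504e-14, -1.5093680534110733e-15, -1.1286067317116846e-15, 5.286274517465632e-17, 4.000437986126701e-17, -9.112090547755774e-19, -6.972752077994577e-19),
    rec_hi = c(-6.972752077994577e-19, 9.112090547755774e-19, 4.000437986126701e-17, -5.286274517465632e-17, -1.1286067317116846e-15, 1.5093680534110733e-15, 2.087175435684504e-14, -2.827804378477004e-14, -2.845914016875714e-13, 3.9104860636051463e-13, 3.051235212860773e-12, -4.257417896733187e-12, -2.6789821104151334e-11, 3.801184928644451e-11, 1.9809120346710113e-10, -2.862848247030911e-10, -1.2590752100024664e-09, 1.8568684752939706e-09, 6.987387541011994e-09, -1.0538640451894265e-08, -3.427757286145719e-08, 5.300650696936342e-08, 1.5013413713144253e-07, -2.3876494051964654e-07, -5.919974641332918e-07, 9.71842353346463e-07, 2.1160757624955858e-06, -3.602893601306652e-06, -6.8957093978400805e-06, 1.2254515725465707e-05, 2.0583278936576757e-05, -3.849201590195014e-05, -5.65441840412094e-05, 0.00011221961943808774, 0.00014390413588042603, -0.0003043599006063343, -0.00034297286150624035, 0.0007668251488526076, 0.0007777201566101956, -0.0017856181989036103, -0.0017080538661070365, 0.003814524076580171, 0.0036793235019773754, -0.0074157782307655, -0.0077852024170722255, 0.013024088005389463, 0.016067283926065306, -0.020539499874530513, -0.03220185256406462, 0.02894925613194684, 0.063646203141354, -0.03633187623818003, -0.13372942834321538, 0.04047709315229175, 0.4473406567537405, -0.7470249379615077, 0.43828475995016103, 0.03474484970544801, -0.12513713600885462, -0.02660154627198806, 0.05596345341137636, 0.01784235415243864, -0.02579684377082798, -0.010430949170645139, 0.01114255210951469, 0.005281202836308561, -0.004323062280774556, -0.0022967107264584086, 0.0014661214569906416, 0.0008488083847885695, -0.00042463732869716845, -0.0002628623520649985, 0.00010248333219568599, 6.692604993754285e-05, -1.9995576397409376e-05, -1.3640357675528054e-05, 3.0247808186844957e-06, 2.1394639250579226e-06, -3.324658385771607e-07, -2.424279845810464e-07, 2.360235756379167e-08, 1.7662495148738494e-08, -8.118993462836169e-10, -6.212814528402405e-10)
  ),
  "bior1.3" = list(
    family = "biorthogonal", vanishing_moments = 1L, orthogonal = FALSE,
    dec_lo = c(-0.08838834764831845, 0.08838834764831845, 0.7071067811865476, 0.7071067811865476, 0.08838834764831845, -0.08838834764831845),
    dec_hi = c(-0.0, 0.0, -0.7071067811865476, 0.7071067811865476, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0),
    rec_hi = c(-0.08838834764831845, -0.08838834764831845, 0.7071067811865476, -0.7071067811865476, 0.08838834764831845, 0.08838834764831845)
  ),
  "bior5.5" = list(
    family = "biorthogonal", vanishing_moments = 5L, orthogonal = FALSE,
    dec_lo = c(0.0, 0.0, 0.03968708834740544, 0.007948108637240322, -0.05446378846823691, 0.34560528195603346, 0.7366601814282105, 0.34560528195603346, -0.05446378846823691, 0.007948108637240322, 0.03968708834740544, 0.0),
    dec_hi = c(-0.013456709459118716, -0.002694966880111507, 0.13670658466432914, -0.09350469740093886, -0.47680326579848425, 0.8995061097486484, -0.47680326579848425, -0.09350469740093886, 0.13670658466432914, -0.002694966880111507, -0.013456709459118716, 0.0),
    rec_lo = c(0.013456709459118716, -0.002694966880111507, -0.13670658466432914, -0.09350469740093886, 0.47680326579848425, 0.8995061097486484, 0.47680326579848425, -0.09350469740093886, -0.13670658466432914, -0.002694966880111507, 0.013456709459118716, 0.0),
    rec_hi = c(0.0, -0.0, 0.03968708834740544, -0.007948108637240322, -0.05446378846823691, -0.34560528195603346, 0.7366601814282105, -0.34560528195603346, -0.05446378846823691, -0.007948108637240322, 0.03968708834740544, -0.0)
  ),
  "rbio1.3" = list(
    family = "reverse biorthogonal", vanishing_moments = 3L, orthogonal = FALSE,
    dec_lo = c(0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0),
    dec_hi = c(0.08838834764831845, 0.08838834764831845, -0.7071067811865476, 0.7071067811865476, -0.08838834764831845, -0.08838834764831845),
    rec_lo = c(-0.08838834764831845, 0.08838834764831845, 0.7071067811865476, 0.7071067811865476, 0.08838834764831845, -0.08838834764831845),
    rec_hi = c(0.0, -0.0, 0.7071067811865476, -0.7071067811865476, 0.0, -0.0)
  ),
  "rbio5.5" = list(
    family = "reverse biorthogonal", vanishing_moments = 5L, orthogonal = FALSE,
    dec_lo = c(0.0, 0.013456709459118716, -0.002694966880111507, -0.13670658466432914, -0.09350469740093886, 0.47680326579848425, 0.8995061097486484, 0.47680326579848425, -0.09350469740093886, -0.13670658466432914, -0.002694966880111507, 0.013456709459118716),
    dec_hi = c(-0.0, 0.03968708834740544, -0.007948108637240322, -0.05446378846823691, -0.34560528195603346, 0.7366601814282105, -0.34560528195603346, -0.05446378846823691, -0.007948108637240322, 0.03968708834740544, -0.0, 0.0),
    rec_lo = c(0.0, 0.03968708834740544, 0.007948108637240322, -0.05446378846823691, 0.34560528195603346, 0.7366601814282105, 0.34560528195603346, -0.05446378846823691, 0.007948108637240322, 0.03968708834740544, 0.0, 0.0),
    rec_hi = c(0.0, -0.013456709459118716, -0.002694966880111507, 0.13670658466432914, -0.09350469740093886, -0.47680326579848425, 0.8995061097486484, -0.47680326579848425, -0.09350469740093886, 0.13670658466432914, -0.002694966880111507, -0.013456709459118716)
  )
)
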