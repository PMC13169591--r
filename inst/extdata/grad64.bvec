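 0.99996948195619950 -0.73716632584708952  0.08735899871868963  0.60752834374973419 -0.98227633262706948  0.84063384741844793 -0.25826193270897990 -0.45773128660962326  0.93100001858368098 -0.91410546282218741  0.41810285895533073  0.29441264332106831 -0.84854815923038041  0.95470012963886230 -0.56017412530653476 -0.12468485781638972  0.73880001116375627 -0.96106837014377122  0.67856964764989636 -0.04399515240757201 -0.60695141993858071  0.93347269981217118 -0.76845836336864037  0.20414992515393746  0.45930864901722418 -0.87380551429880815  0.82631547494486646 -0.34860453217384746 -0.30304178282469396  0.78554596470080973 -0.85010258453101228  0.47079341563788485  0.14591208865746905 -0.67366160223069405  0.83938999680426207 -0.56503391782933443  0.00400715254268646  0.54446634189507104 -0.79541690875856708  0.62674580077440034 -0.13858789567334898 -0.40545553962108866  0.72108754810007381 -0.65258651094747444  0.24983482848259095  0.26515720604467974 -0.62090228372681266  0.64044430822582199 -0.32990462460758030 -0.13308305382248756  0.50081680407217899 -0.58914091467828111  0.37069821058711766  0.02000093919704281 -0.36798042066294256  0.49733209192365768 -0.36211147567801621  0.06067508379922541  0.23000903681628493 -0.35896898896718010  0.28378466013606318 -0.08540397173654808 -0.08931976849519610  0.11484739564873941
 0.00000000000000000  0.67530473982554928 -0.99541073253035506  0.79241314280143971 -0.17375085238485835 -0.53474244330164000  0.96072151672957362 -0.88133373877461940  0.33999971358949088  0.37732944681323854 -0.89346152431267500  0.93863389976947431 -0.49175100285661150 -0.20988814535673411  0.79679004946774334 -0.96218444233684053  0.62266143155665554  0.03974319442301045 -0.67526743174985548  0.95143573293648409 -0.72733065120225115  0.12559743149892119  0.53467331368092486 -0.90746688529300712  0.80155483579211373 -0.27876779185326528 -0.38177870810246850  0.83297270813130664 -0.84253335554515640  0.41286094321941397  0.22408431307756263 -0.73219193155603934  0.84902068716101664 -0.52172140963710134 -0.06954174543891518  0.61078510872988956 -0.82141803916900302  0.60019467561546203 -0.07371906032170680 -0.47567771763601224  0.76180163757803976 -0.64430940857969921  0.19762020157052199  0.33489662296468725 -0.67388655263391650  0.65135207620481972 -0.29425717944780660 -0.19745582519869698  0.56292375461183153 -0.61974457188347432  0.35575679874414029  0.07342349757256444 -0.43551146828902104  0.54846007924459383 -0.37340556852097678  0.02542892421217463  0.29919453375026667 -0.43488917300814350  0.33404429208803266 -0.08259792554072125 -0.16078104370605731  0.26325896509971486 -0.19582559217251091  0.04872412704658658
 0.00781250000000000  0.02343750000000000  0.03906250000000000  0.05468750000000001  0.07031250000000000  0.08593750000000000  0.10156250000000000  0.11718750000000001  0.13281250000000000  0.14843750000000000  0.16406250000000000  0.17968750000000003  0.19531250000000000  0.21093750000000003  0.22656250000000003  0.24218750000000003  0.25781250000000000  0.27343750000000000  0.28906250000000006  0.30468750000000006  0.32031250000000000  0.33593750000000006  0.35156250000000000  0.36718750000000000  0.38281250000000006  0.39843750000000006  0.41406250000000000  0.42968750000000000  0.44531250000000000  0.46093750000000000  0.47656250000000000  0.49218750000000000  0.50781250000000000  0.52343750000000000  0.53906250000000011  0.55468750000000000  0.57031250000000011  0.58593750000000000  0.60156250000000011  0.61718750000000000  0.63281250000000011  0.64843750000000000  0.66406250000000000  0.67968750000000000  0.69531250000000000  0.71093750000000011  0.72656250000000000  0.74218750000000011  0.75781250000000000  0.77343750000000000  0.78906250000000000  0.80468750000000000  0.82031250000000000  0.83593750000000000  0.85156250000000000  0.86718750000000000  0.88281250000000000  0.89843750000000000  0.91406250000000000  0.92968750000000000  0.94531250000000000  0.96093750000000000  0.97656250000000000  0.99218750000000000
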