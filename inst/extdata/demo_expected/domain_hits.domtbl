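#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
GH130.hmm            -           1000 ctg01_g0009          -            451   1.4e-09  100.0   0.1   1   1   1.4e-09 1.360e-09   95.0   0.1     1   608    33   401    33   401 0.90 -
GH26.hmm             -           1000 ctg01_g0010          -            319   3.7e-21  100.0   0.1   1   1   3.7e-21 3.652e-21   95.0   0.1     1   527    21   269    21   269 0.90 -
GH26.hmm             -           1000 ctg01_g0012          -            183   4.7e-15  100.0   0.1   1   1   4.7e-15 4.735e-15   95.0   0.1     1   789    31   133    31   133 0.90 -
GH27.hmm             -           1000 ctg01_g0013          -            306   6.3e-22  100.0   0.1   1   1   6.3e-22 6.308e-22   95.0   0.1     1   894    38   256    38   256 0.90 -
TIGR04056.hmm        -           1000 ctg01_g0014          -            200   1.4e-23  100.0   0.1   1   1   1.4e-23 1.438e-23   95.0   0.1     1   851    17   150    17   150 0.90 -
PF07980.14.hmm       -           1000 ctg01_g0015          -            169   4.5e-14  100.0   0.1   1   1   4.5e-14 4.528e-14   95.0   0.1     1   859     9   119     9   119 0.90 -
GH26.hmm             -           1000 ctg01_g0017          -            383   2.9e-26  100.0   0.1   1   1   2.9e-26 2.879e-26   95.0   0.1     1   705    39   333    39   333 0.90 -
GH5.hmm              -           1000 ctg01_g0018          -            391   4.4e-15  100.0   0.1   1   1   4.4e-15 4.412e-15   95.0   0.1     1   685    23   341    23   341 0.90 -
CE2.hmm              -           1000 ctg01_g0019          -            350   4.8e-28  100.0   0.1   1   1   4.8e-28 4.756e-28   95.0   0.1     1   865    19   300    19   300 0.90 -
TIGR04056.hmm        -           1000 ctg01_g0030          -            268   2.5e-25  100.0   0.1   1   1   2.5e-25 2.516e-25   95.0   0.1     1   772    26   218    26   218 0.90 -
PF12771.10.hmm       -           1000 ctg01_g0031          -            423   1.4e-27  100.0   0.1   1   1   1.4e-27 1.421e-27   95.0   0.1     1   795    30   373    30   373 0.90 -
#
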