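>ETS_SYNTH ets-core-synthetic
A [  4  80   2  95   2   2  90  30 ]
C [  6   5   3   1   1   1   4  20 ]
G [ 85  10  92   2  95  95   2  25 ]
T [  5   5   3   2   2   2   4  25 ]
>NFKB_SYNTH nfkb-like-synthetic
A [  2   2   2  60  25  10   2   2  10 ]
C [  3   3   3  10  25  30  90  90  75 ]
G [ 92  92  92  20  25  30   4   4   5 ]
T [  3   3   3  10  25  30   4   4  10 ]
>DECOY_SYNTH decoy-synthetic
A [ 30  10  45  20  35  15  25 ]
C [ 25  40  15  30  20  35  25 ]
G [ 25  15  20  30  25  30  25 ]
T [ 20  35  20  20  20  20  25 ]
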