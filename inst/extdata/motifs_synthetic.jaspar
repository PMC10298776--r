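>SYN0001.1 ETSlike
A [ 10  5 90  2  1  5 30 ]
C [ 20  5  4  2  1  5 30 ]
G [ 40 85  4 94  1 85 20 ]
T [ 30  5  2  2 97  5 20 ]
>SYN0002.1 IRFlike
A [ 80  80  5  2 70 70  5  2 ]
C [  5   5  5  2 10 10  5  2 ]
G [  5   5  5 94 10 10  5 94 ]
T [ 10  10 85  2 10 10 85  2 ]
>SYN0003.1 SPI1like
A [ 30  60  2 90 90  5 ]
C [ 20  10  2  3  3  5 ]
G [ 30  20 94  4  4 85 ]
T [ 20  10  2  3  3  5 ]
>SYN0004.1 RUNXlike
A [  5 90  2  2 60  5 ]
C [ 80  4  2 90 20  5 ]
G [  5  3 94  4 10  5 ]
T [ 10  3  2  4 10 85 ]
>SYN0005.1 CEBPlike
A [  5 90  2  2  5 70  5 ]
C [  5  4  2 90  5 10  5 ]
G [  5  3  2  4 85 10  5 ]
T [ 85  3 94  4  5 10 85 ]
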