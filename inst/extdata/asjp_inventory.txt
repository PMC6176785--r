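# Sound-class inventory and modifier conventions.
# One `key value...` line per entry; whitespace-separated.
#   symbols  the sound-class codes (41 by default)
#   drop     modifier characters removed during normalization
#   join2    marker reducing the preceding two symbols to the first
#   join3    marker reducing the preceding three symbols to the first
symbols i e E 3 a u o p b m f v w 8 4 t d s z c n r l S Z C j T 5 L y k g x N q G X 7 h !
drop " * ' %
join2 ~
join3 $
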