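####################
#..................#
#..................#
#..G............G..#
#..................#
#..................#
#..................#
#..................#
#..................#
#..................#
#........S.........#
#..................#
#..................#
#..................#
#..................#
#..................#
#..G............G..#
#..................#
#..................#
####################
G=1
wall_penalty=0
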