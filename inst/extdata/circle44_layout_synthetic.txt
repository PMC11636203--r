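# Synthetic circular 44-bit tag layout, 10 x 10 cells.
# This grid is a stand-in constructed from the published description of the
# family (10 x 10 cells, 44 data bits, raster-circle shape): cell roles are
# assigned by distance from the grid centre, giving a white outer ring (w),
# a black detection ring (b), 44 data cells (d) and 20 ignored corner cells
# (x). It is NOT the upstream family's grid, whose exact corner layout is
# not restated in text form; codewords rendered with this layout are
# internally consistent but not interchangeable with the upstream family.
# Roles: w = fixed white, b = fixed black, d = data bit, x = ignored.
xxxwwwwxxx
xwbbddbbwx
xbddddddbx
wbddddddbw
wddddddddw
wddddddddw
wbddddddbw
xbddddddbx
xwbbddbbwx
xxxwwwwxxx
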