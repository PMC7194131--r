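ply
format ascii 1.0
element vertex 8
property double x
property double y
property double z
property int surface_label
element face 12
property list uchar int vertex_indices
end_header
0 0 0 2
1 0 0 2
1 1 0 2
0 1 0 2
0 0 1 2
1 0 1 2
1 1 1 2
0 1 1 2
3 0 2 1
3 0 3 2
3 4 5 6
3 4 6 7
3 0 1 5
3 0 5 4
3 1 2 6
3 1 6 5
3 2 3 7
3 2 7 6
3 3 0 4
3 3 4 7
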