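$MeshFormat
4.1 0 8
$EndMeshFormat
$PhysicalNames
5
2 2 "z0"
2 3 "y0"
2 4 "x0"
2 5 "diag"
3 1 "volume"
$EndPhysicalNames
$Entities
0 0 4 1
2 0 0 0 1 1 1 1 2 0
3 0 0 0 1 1 1 1 3 0
4 0 0 0 1 1 1 1 4 0
5 0 0 0 1 1 1 1 5 0
1 0 0 0 1 1 1 1 1 0
$EndEntities
$Nodes
1 4 1 4
3 1 0 4
1
2
3
4
0 0 0
1 0 0
0 1 0
0 0 1
$EndNodes
$Elements
5 5 1 5
2 2 2 1
1 1 2 3
2 3 2 1
2 1 2 4
2 4 2 1
3 1 3 4
2 5 2 1
4 2 3 4
3 1 4 1
5 1 2 3 4
$EndElements
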