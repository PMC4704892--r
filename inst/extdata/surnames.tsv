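name	weight
Smith	828
Johnson	655
Williams	540
Brown	433
Jones	429
Garcia	396
Miller	355
Davis	335
Rodriguez	324
Martinez	323
Hernandez	261
Lopez	252
Gonzalez	248
Wilson	242
Anderson	236
Thomas	226
Taylor	225
Moore	217
Jackson	212
Martin	211
Lee	206
Perez	198
Thompson	197
White	195
Harris	189
Sanchez	188
Clark	178
Ramirez	173
Lewis	170
Robinson	167
Walker	166
Young	160
Allen	154
King	153
Wright	152
Scott	150
Torres	149
Nguyen	148
Hill	147
Flores	145
Green	142
Adams	140
Nelson	139
Baker	138
Hall	135
Rivera	133
Campbell	132
Mitchell	131
Carter	130
Roberts	127
Gomez	125
Phillips	122
Evans	121
Turner	119
Diaz	118
Parker	116
Cruz	115
Edwards	113
Collins	112
Reyes	111
Stewart	110
Morris	109
Morales	108
Murphy	107
Cook	106
Rogers	105
Gutierrez	103
Ortiz	102
Morgan	101
Cooper	100
Peterson	99
Bailey	98
Reed	97
Kelly	96
Howard	95
Ramos	94
Kim	93
Cox	92
Ward	91
Richardson	90
Watson	89
Brooks	88
Chavez	87
Wood	86
James	85
Bennett	84
Gray	83
Mendoza	82
Ruiz	81
Hughes	80
Price	79
Alvarez	78
Castillo	77
Sanders	76
Patel	75
Myers	74
Long	73
Ross	72
Foster	71
Jimenez	70
Powell	69
Jenkins	68
Perry	67
Russell	66
Sullivan	65
Bell	64
Coleman	63
Butler	62
Henderson	61
Barnes	60
Gonzales	59
Fisher	58
Vasquez	57
Simmons	56
Romero	55
Jordan	54
Patterson	53
Alexander	52
Hamilton	51
Graham	50
Reynolds	49
Griffin	48
Wallace	47
Moreno	46
West	45
Cole	44
Hayes	43
Bryant	42
Herrera	41
Gibson	40
Ellis	39
Tran	38
Medina	37
Aguilar	36
Stevens	35
Murray	34
Ford	33
Castro	32
Marshall	31
Owens	30
Harrison	29
Fernandez	28
McDonald	27
Woods	26
Washington	25
Kennedy	24
Wells	23
Vargas	22
Henry	21
Chen	20
Freeman	19
Webb	18
Tucker	17
Guzman	16
Burns	15
Crawford	14
Olson	13
Simpson	12
Porter	11
Hunter	10
Gordon	9
Mendez	8
Silva	7
Shaw	6
Snyder	5
Mason	4
Dixon	3
Munoz	2
Hunt	2
Hicks	2
Holmes	2
Palmer	2
Wagner	2
Black	2
Robertson	2
Boyd	2
Rose	2
Stone	2
Salazar	2
Fox	2
Warren	2
Mills	2
Meyer	2
Rice	2
Schmidt	2
Garza	2
Daniels	2
Ferguson	2
Nichols	2
Stephens	2
Soto	2
Weaver	2
Ryan	2
Gardner	2
Payne	2
Grant	2
Dunn	2
Kelley	2
Spencer	2
Hawkins	2
Arnold	2
Pierce	2
Vazquez	2
Hansen	2
Peters	2
Santos	2
Hart	2
Bradley	2
Knight	2
Elliott	2
Cunningham	2
Duncan	2
Armstrong	2
Hudson	2
Carroll	2
Lane	2
Riley	2
Andrews	2
Alvarado	2
Ray	2
Delgado	2
Berry	2
Perkins	2
Hoffman	2
Johnston	2
Matthews	2
Pena	2
Richards	2
Contreras	2
Willis	2
Carpenter	2
Lawrence	2
Sandoval	2
Guerrero	2
George	2
Chapman	2
Rios	2
Estrada	2
Ortega	2
Watkins	2
Greene	2
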