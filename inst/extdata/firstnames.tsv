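name	weight
James	331
Robert	314
John	306
Michael	298
David	244
William	239
Richard	175
Joseph	163
Thomas	148
Charles	136
Mary	267
Patricia	160
Jennifer	149
Linda	145
Elizabeth	142
Barbara	138
Susan	111
Jessica	104
Sarah	97
Karen	94
Christopher	130
Daniel	126
Matthew	116
Anthony	106
Mark	105
Donald	103
Steven	100
Paul	94
Andrew	92
Joshua	91
Nancy	93
Lisa	92
Margaret	85
Betty	84
Sandra	83
Ashley	82
Dorothy	79
Kimberly	78
Emily	77
Donna	76
Kenneth	89
Kevin	87
Brian	86
George	84
Edward	80
Ronald	79
Timothy	77
Jason	76
Jeffrey	74
Ryan	72
Michelle	75
Carol	74
Amanda	73
Melissa	71
Deborah	70
Stephanie	69
Rebecca	68
Laura	67
Sharon	66
Cynthia	65
Jacob	70
Gary	69
Nicholas	67
Eric	66
Jonathan	64
Stephen	63
Larry	62
Justin	61
Scott	60
Brandon	59
Kathleen	64
Amy	63
Shirley	62
Angela	61
Helen	60
Anna	59
Brenda	58
Pamela	57
Nicole	56
Emma	55
Benjamin	58
Samuel	57
Gregory	55
Frank	54
Alexander	53
Raymond	52
Patrick	51
Jack	50
Dennis	49
Jerry	48
Samantha	54
Katherine	53
Christine	52
Debra	51
Rachel	50
Catherine	49
Carolyn	48
Janet	47
Ruth	46
Maria	45
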