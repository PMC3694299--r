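dataset	trait	population	bin	step	label	count	errors	parent_label
training	eye	AA	brown	1	brown	31	0	NA
training	eye	AA	brown	1	not_blue	12	0	NA
training	eye	AA	brown	2	brown	8	0	not_blue
training	eye	AA	brown	2	not_blue	4	0	not_blue
training	eye	SA	brown	1	brown	21	0	NA
training	eye	SA	brown	1	not_blue	6	0	NA
training	eye	EA	brown	1	brown	34	0	NA
training	eye	EA	brown	1	not_blue	1	0	NA
training	eye	E	blue	1	blue	11	0	NA
training	eye	E	blue	1	green	2	2	NA
training	eye	E	blue	1	not_brown	175	0	NA
training	eye	E	blue	2	blue	37	0	not_brown
training	eye	E	blue	2	not_brown	138	0	not_brown
training	eye	E	blue	1	not_blue	7	7	NA
training	eye	E	green	1	green	1	0	NA
training	eye	E	green	1	blue	1	1	NA
training	eye	E	green	1	not_blue	92	0	NA
training	eye	E	green	2	brown	5	5	not_blue
training	eye	E	green	2	not_blue	87	0	not_blue
training	eye	E	green	1	not_brown	76	0	NA
training	eye	E	green	2	blue	6	6	not_brown
training	eye	E	green	2	not_brown	70	0	not_brown
training	eye	E	brown	1	brown	2	0	NA
training	eye	E	brown	1	not_blue	187	0	NA
training	eye	E	brown	2	brown	24	0	not_blue
training	eye	E	brown	2	not_blue	163	0	not_blue
training	eye	E	brown	1	not_brown	1	1	NA
training	eye	mix	blue	1	not_brown	10	0	NA
training	eye	mix	blue	2	blue	2	0	not_brown
training	eye	mix	blue	2	not_brown	8	0	not_brown
training	eye	mix	blue	1	not_blue	1	1	NA
training	eye	mix	green	1	green	2	0	NA
training	eye	mix	green	1	brown	1	1	NA
training	eye	mix	green	1	not_blue	10	0	NA
training	eye	mix	green	1	not_brown	7	0	NA
training	eye	mix	green	2	blue	1	1	not_brown
training	eye	mix	green	2	not_brown	6	0	not_brown
training	eye	mix	brown	1	brown	45	0	NA
training	eye	mix	brown	1	not_blue	67	0	NA
training	eye	mix	brown	2	brown	14	0	not_blue
training	eye	mix	brown	2	not_blue	53	0	not_blue
test	eye	AA	brown	1	brown	7	0	NA
test	eye	AA	brown	1	not_blue	1	0	NA
test	eye	AA	brown	2	brown	1	0	not_blue
test	eye	SA	green	1	green	1	0	NA
test	eye	SA	brown	1	brown	7	0	NA
test	eye	SA	brown	1	not_blue	1	0	NA
test	eye	SA	brown	2	brown	1	0	not_blue
test	eye	EA	brown	1	brown	10	0	NA
test	eye	E	blue	1	blue	3	0	NA
test	eye	E	blue	1	not_brown	46	0	NA
test	eye	E	blue	2	blue	10	0	not_brown
test	eye	E	blue	2	not_brown	36	0	not_brown
test	eye	E	blue	1	not_blue	2	2	NA
test	eye	E	green	1	green	1	0	NA
test	eye	E	green	1	not_blue	21	0	NA
test	eye	E	green	2	brown	2	2	not_blue
test	eye	E	green	2	not_blue	19	0	not_blue
test	eye	E	green	1	not_brown	16	0	NA
test	eye	E	green	2	blue	1	1	not_brown
test	eye	E	green	2	not_brown	15	0	not_brown
test	eye	E	brown	1	not_blue	25	0	NA
test	eye	E	brown	2	brown	3	0	not_blue
test	eye	E	brown	2	not_blue	22	0	not_blue
test	eye	mix	blue	1	blue	1	0	NA
test	eye	mix	blue	1	not_brown	3	0	NA
test	eye	mix	green	1	green	2	0	NA
test	eye	mix	green	1	not_blue	6	0	NA
test	eye	mix	brown	1	brown	24	0	NA
test	eye	mix	brown	1	not_blue	35	0	NA
test	eye	mix	brown	2	brown	12	0	not_blue
test	eye	mix	brown	2	not_blue	23	0	not_blue
training	skin	AA	dark	1	not_light	15	0	NA
training	skin	AA	dark	1	inconclusive	24	0	NA
training	skin	AA	medium	1	not_light	1	0	NA
training	skin	AA	medium	1	inconclusive	3	0	NA
training	skin	SA	dark	1	not_dark	1	1	NA
training	skin	SA	dark	1	inconclusive	4	0	NA
training	skin	SA	medium	1	not_dark	2	0	NA
training	skin	SA	medium	1	inconclusive	19	0	NA
training	skin	SA	light	1	inconclusive	1	0	NA
training	skin	EA	light	1	not_dark	9	0	NA
training	skin	EA	light	1	inconclusive	21	0	NA
training	skin	EA	medium	1	not_dark	1	0	NA
training	skin	EA	medium	1	inconclusive	4	0	NA
training	skin	E	light	1	light	244	0	NA
training	skin	E	light	1	not_dark	268	0	NA
training	skin	E	light	1	inconclusive	43	0	NA
training	skin	mix	dark	1	not_light	5	0	NA
training	skin	mix	dark	1	not_dark	3	3	NA
training	skin	mix	dark	1	inconclusive	14	0	NA
training	skin	mix	medium	1	not_dark	7	0	NA
training	skin	mix	medium	1	not_light	4	0	NA
training	skin	mix	medium	1	inconclusive	37	0	NA
training	skin	mix	light	1	light	11	0	NA
training	skin	mix	light	1	not_dark	29	0	NA
training	skin	mix	light	1	inconclusive	33	0	NA
test	skin	AA	dark	1	not_light	4	0	NA
test	skin	AA	dark	1	inconclusive	4	0	NA
test	skin	SA	dark	1	inconclusive	1	0	NA
test	skin	SA	medium	1	inconclusive	7	0	NA
test	skin	SA	light	1	inconclusive	1	0	NA
test	skin	EA	light	1	not_dark	1	0	NA
test	skin	EA	light	1	inconclusive	9	0	NA
test	skin	E	light	1	light	60	0	NA
test	skin	E	light	1	not_dark	47	0	NA
test	skin	E	light	1	inconclusive	7	0	NA
test	skin	mix	dark	1	not_light	1	0	NA
test	skin	mix	dark	1	inconclusive	4	0	NA
test	skin	mix	medium	1	not_dark	4	0	NA
test	skin	mix	medium	1	inconclusive	14	0	NA
test	skin	mix	light	1	light	3	0	NA
test	skin	mix	light	1	not_dark	11	0	NA
test	skin	mix	light	1	inconclusive	34	0	NA
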