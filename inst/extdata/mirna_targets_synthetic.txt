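GENE019
GENE020
GENE024
GENE031
GENE036
GENE037
GENE042
GENE049
GENE050
GENE060
GENE061
GENE070
GENE073
GENE081
GENE086
GENE093
GENE107
GENE108
GENE110
GENE125
GENE127
GENE129
GENE132
GENE135
GENE140
GENE145
GENE152
GENE162
GENE168
GENE175
GENE176
GENE185
GENE186
GENE194
GENE195
GENE201
GENE202
GENE207
GENE209
GENE210
GENE226
GENE230
GENE233
GENE238
GENE239
GENE244
GENE245
GENE249
GENE253
GENE255
GENE257
GENE268
GENE271
GENE272
GENE273
GENE285
GENE289
GENE294
GENE301
GENE304
GENE306
GENE317
GENE320
GENE322
GENE323
GENE329
GENE350
GENE351
GENE354
GENE360
GENE364
GENE369
GENE374
GENE377
GENE380
GENE386
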