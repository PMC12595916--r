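"dimensionality","in_channels","layer","kernel_volume","cin","cout","weights","biases","total"
2,1,"enc0_conv1",9,1,8,72,8,80
2,1,"enc0_conv2",9,8,8,576,8,584
2,1,"enc1_conv1",9,8,16,1152,16,1168
2,1,"enc1_conv2",9,16,16,2304,16,2320
2,1,"enc2_conv1",9,16,32,4608,32,4640
2,1,"enc2_conv2",9,32,32,9216,32,9248
2,1,"enc3_conv1",9,32,64,18432,64,18496
2,1,"enc3_conv2",9,64,64,36864,64,36928
2,1,"bottleneck_conv1",9,64,128,73728,128,73856
2,1,"bottleneck_conv2",9,128,128,147456,128,147584
2,1,"dec3_upconv",4,128,64,32768,64,32832
2,1,"dec3_conv1",9,128,64,73728,64,73792
2,1,"dec3_conv2",9,64,64,36864,64,36928
2,1,"dec2_upconv",4,64,32,8192,32,8224
2,1,"dec2_conv1",9,64,32,18432,32,18464
2,1,"dec2_conv2",9,32,32,9216,32,9248
2,1,"dec1_upconv",4,32,16,2048,16,2064
2,1,"dec1_conv1",9,32,16,4608,16,4624
2,1,"dec1_conv2",9,16,16,2304,16,2320
2,1,"dec0_upconv",4,16,8,512,8,520
2,1,"dec0_conv1",9,16,8,1152,8,1160
2,1,"dec0_conv2",9,8,8,576,8,584
2,1,"output_conv",1,8,1,8,1,9
2,4,"enc0_conv1",9,4,8,288,8,296
2,4,"enc0_conv2",9,8,8,576,8,584
2,4,"enc1_conv1",9,8,16,1152,16,1168
2,4,"enc1_conv2",9,16,16,2304,16,2320
2,4,"enc2_conv1",9,16,32,4608,32,4640
2,4,"enc2_conv2",9,32,32,9216,32,9248
2,4,"enc3_conv1",9,32,64,18432,64,18496
2,4,"enc3_conv2",9,64,64,36864,64,36928
2,4,"bottleneck_conv1",9,64,128,73728,128,73856
2,4,"bottleneck_conv2",9,128,128,147456,128,147584
2,4,"dec3_upconv",4,128,64,32768,64,32832
2,4,"dec3_conv1",9,128,64,73728,64,73792
2,4,"dec3_conv2",9,64,64,36864,64,36928
2,4,"dec2_upconv",4,64,32,8192,32,8224
2,4,"dec2_conv1",9,64,32,18432,32,18464
2,4,"dec2_conv2",9,32,32,9216,32,9248
2,4,"dec1_upconv",4,32,16,2048,16,2064
2,4,"dec1_conv1",9,32,16,4608,16,4624
2,4,"dec1_conv2",9,16,16,2304,16,2320
2,4,"dec0_upconv",4,16,8,512,8,520
2,4,"dec0_conv1",9,16,8,1152,8,1160
2,4,"dec0_conv2",9,8,8,576,8,584
2,4,"output_conv",1,8,1,8,1,9
3,1,"enc0_conv1",27,1,8,216,8,224
3,1,"enc0_conv2",27,8,8,1728,8,1736
3,1,"enc1_conv1",27,8,16,3456,16,3472
3,1,"enc1_conv2",27,16,16,6912,16,6928
3,1,"enc2_conv1",27,16,32,13824,32,13856
3,1,"enc2_conv2",27,32,32,27648,32,27680
3,1,"enc3_conv1",27,32,64,55296,64,55360
3,1,"enc3_conv2",27,64,64,110592,64,110656
3,1,"bottleneck_conv1",27,64,128,221184,128,221312
3,1,"bottleneck_conv2",27,128,128,442368,128,442496
3,1,"dec3_upconv",8,128,64,65536,64,65600
3,1,"dec3_conv1",27,128,64,221184,64,221248
3,1,"dec3_conv2",27,64,64,110592,64,110656
3,1,"dec2_upconv",8,64,32,16384,32,16416
3,1,"dec2_conv1",27,64,32,55296,32,55328
3,1,"dec2_conv2",27,32,32,27648,32,27680
3,1,"dec1_upconv",8,32,16,4096,16,4112
3,1,"dec1_conv1",27,32,16,13824,16,13840
3,1,"dec1_conv2",27,16,16,6912,16,6928
3,1,"dec0_upconv",8,16,8,1024,8,1032
3,1,"dec0_conv1",27,16,8,3456,8,3464
3,1,"dec0_conv2",27,8,8,1728,8,1736
3,1,"output_conv",1,8,1,8,1,9
3,4,"enc0_conv1",27,4,8,864,8,872
3,4,"enc0_conv2",27,8,8,1728,8,1736
3,4,"enc1_conv1",27,8,16,3456,16,3472
3,4,"enc1_conv2",27,16,16,6912,16,6928
3,4,"enc2_conv1",27,16,32,13824,32,13856
3,4,"enc2_conv2",27,32,32,27648,32,27680
3,4,"enc3_conv1",27,32,64,55296,64,55360
3,4,"enc3_conv2",27,64,64,110592,64,110656
3,4,"bottleneck_conv1",27,64,128,221184,128,221312
3,4,"bottleneck_conv2",27,128,128,442368,128,442496
3,4,"dec3_upconv",8,128,64,65536,64,65600
3,4,"dec3_conv1",27,128,64,221184,64,221248
3,4,"dec3_conv2",27,64,64,110592,64,110656
3,4,"dec2_upconv",8,64,32,16384,32,16416
3,4,"dec2_conv1",27,64,32,55296,32,55328
3,4,"dec2_conv2",27,32,32,27648,32,27680
3,4,"dec1_upconv",8,32,16,4096,16,4112
3,4,"dec1_conv1",27,32,16,13824,16,13840
3,4,"dec1_conv2",27,16,16,6912,16,6928
3,4,"dec0_upconv",8,16,8,1024,8,1032
3,4,"dec0_conv1",27,16,8,3456,8,3464
3,4,"dec0_conv2",27,8,8,1728,8,1736
3,4,"output_conv",1,8,1,8,1,9
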