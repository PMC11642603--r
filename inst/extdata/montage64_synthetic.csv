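channel,x,y
E01,0,0
E02,0.229749,0.101244
E03,0.199979,-0.14646
E04,-0.026733,-0.245356
E05,-0.227795,-0.100383
E06,-0.203407,0.148971
E07,0.027425,0.251703
E08,0.366036,-0.334665
E09,0.151165,-0.477592
E10,-0.108196,-0.490609
E11,-0.333947,-0.36525
E12,-0.482823,-0.152821
E13,-0.482368,0.106378
E14,-0.371989,0.340108
E15,-0.150596,0.475792
E16,0.107163,0.485926
E17,0.340827,0.372774
E18,0.470561,0.14894
E19,0.494167,-0.108981
E20,-0.242532,-0.71839
E21,-0.442331,-0.594408
E22,-0.613749,-0.435284
E23,-0.721818,-0.225445
E24,-0.74022,0.008461
E25,-0.715556,0.241575
E26,-0.604555,0.449881
E27,-0.428414,0.604061
E28,-0.225837,0.723073
E29,0.008579,0.750551
E30,0.237269,0.702803
E31,0.45316,0.608961
E32,0.609774,0.432465
E33,0.709972,0.221745
E34,0.759682,-0.008684
E35,0.705637,-0.238226
E36,0.598814,-0.445609
E37,0.439336,-0.619462
E38,0.221353,-0.708717
E39,-0.008566,-0.749351
E40,-0.983398,-0.08823
E41,-0.992169,0.161997
E42,-0.925616,0.405801
E43,-0.7799,0.610931
E44,-0.604761,0.787377
E45,-0.397478,0.930667
E46,-0.15213,0.991074
E47,0.097569,0.982168
E48,0.343972,0.941311
E49,0.572913,0.83443
E50,0.748169,0.653286
E51,0.884545,0.445399
E52,0.987075,0.215701
E53,1.005102,-0.036385
E54,0.94694,-0.280015
E55,0.85739,-0.512593
E56,0.712824,-0.719654
E57,0.503024,-0.859898
E58,0.27125,-0.950544
E59,0.02686,-1.007734
E60,-0.224683,-0.98313
E61,-0.45307,-0.878815
E62,-0.662052,-0.743771
E63,-0.840425,-0.565313
E64,-0.941952,-0.334059
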