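name	x	y	z
1L	-0.154508497	0.975528258	0.156434465
1R	0.154508497	0.975528258	0.156434465
2L	-0.448401123	0.880036755	0.156434465
2R	0.448401123	0.880036755	0.156434465
3L	-0.698401123	0.698401123	0.156434465
3R	0.698401123	0.698401123	0.156434465
4L	-0.880036755	0.448401123	0.156434465
4R	0.880036755	0.448401123	0.156434465
5L	-0.975528258	0.154508497	0.156434465
5R	0.975528258	0.154508497	0.156434465
6L	-0.975528258	-0.154508497	0.156434465
6R	0.975528258	-0.154508497	0.156434465
7L	-0.880036755	-0.448401123	0.156434465
7R	0.880036755	-0.448401123	0.156434465
8L	-0.698401123	-0.698401123	0.156434465
8R	0.698401123	-0.698401123	0.156434465
9L	-0.448401123	-0.880036755	0.156434465
9R	0.448401123	-0.880036755	0.156434465
10L	-0.154508497	-0.975528258	0.156434465
10R	0.154508497	-0.975528258	0.156434465
11L	-0.154721659	0.877470133	 0.4539905
11R	0.154721659	0.877470133	 0.4539905
12L	-0.445503262	0.771634285	 0.4539905
12R	0.445503262	0.771634285	 0.4539905
13L	-0.682550597	0.572727954	 0.4539905
13R	0.682550597	0.572727954	 0.4539905
14L	-0.837272256	0.304742179	 0.4539905
14R	0.837272256	0.304742179	 0.4539905
15L	-0.891006524	5.45584144e-17	 0.4539905
15R	0.891006524	5.45584144e-17	 0.4539905
16L	-0.837272256	-0.304742179	 0.4539905
16R	0.837272256	-0.304742179	 0.4539905
17L	-0.682550597	-0.572727954	 0.4539905
17R	0.682550597	-0.572727954	 0.4539905
18L	-0.445503262	-0.771634285	 0.4539905
18R	0.445503262	-0.771634285	 0.4539905
19L	-0.154721659	-0.877470133	 0.4539905
19R	0.154721659	-0.877470133	 0.4539905
20L	-0.157346061	0.689378138	0.707106781
20R	0.157346061	0.689378138	0.707106781
21L	-0.440873867	0.552838343	0.707106781
21R	0.440873867	0.552838343	0.707106781
22L	-0.637081196	0.306802134	0.707106781
22R	0.637081196	0.306802134	0.707106781
23L	-0.707106781	4.32978028e-17	0.707106781
23R	0.707106781	4.32978028e-17	0.707106781
24L	-0.637081196	-0.306802134	0.707106781
24R	0.637081196	-0.306802134	0.707106781
25L	-0.440873867	-0.552838343	0.707106781
25R	0.440873867	-0.552838343	0.707106781
26L	-0.157346061	-0.689378138	0.707106781
26R	0.157346061	-0.689378138	0.707106781
1Z	        -0	 0.4539905	0.891006524
27L	-0.291819468	 0.3477769	0.891006524
27R	0.291819468	 0.3477769	0.891006524
28L	-0.447093364	0.078834623	0.891006524
28R	0.447093364	0.078834623	0.891006524
29L	-0.393167306	-0.22699525	0.891006524
29R	0.393167306	-0.22699525	0.891006524
30L	-0.155273896	-0.426611523	0.891006524
30R	0.155273896	-0.426611523	0.891006524
2Z	        -0	0.156434465	0.987688341
31L	-0.135476221	-0.0782172325	0.987688341
31R	0.135476221	-0.0782172325	0.987688341
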