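Type	SBS1	SBS5	FLAT
A[C>A]A	0.000516528925619835	0.00917791516677465	0.0104166666666667
A[C>A]C	0.000516528925619835	0.00966234894818652	0.0104166666666667
A[C>A]G	0.000516528925619835	0.0101268382665696	0.0104166666666667
A[C>A]T	0.000516528925619835	0.0105619198585005	0.0104166666666667
C[C>A]A	0.000516528925619835	0.0109587295982563	0.0104166666666667
C[C>A]C	0.000516528925619835	0.0113091830908947	0.0104166666666667
C[C>A]G	0.000516528925619835	0.0116061403795055	0.0104166666666667
C[C>A]T	0.000516528925619835	0.0118435514109737	0.0104166666666667
G[C>A]A	0.000516528925619835	0.0120165792966098	0.0104166666666667
G[C>A]C	0.000516528925619835	0.012121698856401	0.0104166666666667
G[C>A]G	0.000516528925619835	0.0121567684391922	0.0104166666666667
G[C>A]T	0.000516528925619835	0.0121210735555711	0.0104166666666667
T[C>A]A	0.000516528925619835	0.0120153414345033	0.0104166666666667
T[C>A]C	0.000516528925619835	0.0118417262071484	0.0104166666666667
T[C>A]G	0.000516528925619835	0.0116037650197135	0.0104166666666667
T[C>A]T	0.000516528925619835	0.011306305969479	0.0104166666666667
A[C>G]A	0.000516528925619835	0.01095540933219	0.0104166666666667
A[C>G]C	0.000516528925619835	0.010558224093155	0.0104166666666667
A[C>G]G	0.000516528925619835	0.0101228422975428	0.0104166666666667
A[C>G]T	0.000516528925619835	0.00965813418726995	0.0104166666666667
C[C>G]A	0.000516528925619835	0.00917356748331179	0.0104166666666667
C[C>G]C	0.000516528925619835	0.00867901449528725	0.0104166666666667
C[C>G]G	0.000516528925619835	0.00818455098816503	0.0104166666666667
C[C>G]T	0.000516528925619835	0.00770025090387656	0.0104166666666667
G[C>G]A	0.000516528925619835	0.00723598112007048	0.0104166666666667
G[C>G]C	0.000516528925619835	0.00680120042748708	0.0104166666666667
G[C>G]G	0.000516528925619835	0.00640476682148273	0.0104166666666667
G[C>G]T	0.000516528925619835	0.00605475703384659	0.0104166666666667
T[C>G]A	0.000516528925619835	0.00575830198167422	0.0104166666666667
T[C>G]C	0.000516528925619835	0.00552144148577715	0.0104166666666667
T[C>G]G	0.000516528925619835	0.00534900121851976	0.0104166666666667
T[C>G]T	0.000516528925619835	0.00524449438808419	0.0104166666666667
A[C>T]A	0.00413223140495868	0.00729407022707556	0.0104166666666667
A[C>T]C	0.00413223140495868	0.00734491840540379	0.0104166666666667
A[C>T]G	0.227272727272727	0.00749380072400378	0.0104166666666667
A[C>T]T	0.00413223140495868	0.00773768393206817	0.0104166666666667
C[C>T]A	0.00413223140495868	0.00807159928015295	0.0104166666666667
C[C>T]C	0.00413223140495868	0.0084887437508905	0.0104166666666667
C[C>T]G	0.227272727272727	0.00898061866012173	0.0104166666666667
C[C>T]T	0.00413223140495868	0.0095372028046603	0.0104166666666667
G[C>T]A	0.00413223140495868	0.0101471566290663	0.0104166666666667
G[C>T]C	0.00413223140495868	0.010798053251842	0.0104166666666667
G[C>T]G	0.227272727272727	0.0114766316442427	0.0104166666666667
G[C>T]T	0.00413223140495868	0.0121690668035686	0.0104166666666667
T[C>T]A	0.00413223140495868	0.0128612514165682	0.0104166666666667
T[C>T]C	0.00413223140495868	0.0135390832744906	0.0104166666666667
T[C>T]G	0.227272727272727	0.0141887525841406	0.0104166666666667
T[C>T]T	0.00413223140495868	0.0147970233214116	0.0104166666666667
A[T>A]A	0.000516528925619835	0.0109653592108191	0.0104166666666667
A[T>A]C	0.000516528925619835	0.0113149247338108	0.0104166666666667
A[T>A]G	0.000516528925619835	0.011610877075533	0.0104166666666667
A[T>A]T	0.000516528925619835	0.0118471866571349	0.0104166666666667
C[T>A]A	0.000516528925619835	0.0120190390302932	0.0104166666666667
C[T>A]C	0.000516528925619835	0.0121229329642737	0.0104166666666667
C[T>A]G	0.000516528925619835	0.0121567517781832	0.0104166666666667
C[T>A]T	0.000516528925619835	0.0121198064651232	0.0104166666666667
G[T>A]A	0.000516528925619835	0.0120128497296572	0.0104166666666667
G[T>A]C	0.000516528925619835	0.0118380606526008	0.0104166666666667
G[T>A]G	0.000516528925619835	0.0115990002955633	0.0104166666666667
G[T>A]T	0.000516528925619835	0.0113005391497342	0.0104166666666667
T[T>A]A	0.000516528925619835	0.0109487579070321	0.0104166666666667
T[T>A]C	0.000516528925619835	0.0105508235752555	0.0104166666666667
T[T>A]G	0.000516528925619835	0.0101148434611985	0.0104166666666667
T[T>A]T	0.000516528925619835	0.00964969999660606	0.0104166666666667
A[T>C]A	0.000516528925619835	0.0183297395442711	0.0104166666666667
A[T>C]C	0.000516528925619835	0.0173404609324711	0.0104166666666667
A[T>C]G	0.000516528925619835	0.0163517192049406	0.0104166666666667
A[T>C]T	0.000516528925619835	0.0153836584706072	0.0104166666666667
C[T>C]A	0.000516528925619835	0.014456001494616	0.0104166666666667
C[T>C]C	0.000516528925619835	0.0135876478769857	0.0104166666666667
C[T>C]G	0.000516528925619835	0.0127962890020023	0.0104166666666667
C[T>C]T	0.000516528925619835	0.0120980476031713	0.0104166666666667
G[T>C]A	0.000516528925619835	0.0115071492870432	0.0104166666666667
G[T>C]C	0.000516528925619835	0.0110356327081158	0.0104166666666667
G[T>C]G	0.000516528925619835	0.0106931042995585	0.0104166666666667
G[T>C]T	0.000516528925619835	0.0104865425567464	0.0104166666666667
T[T>C]A	0.000516528925619835	0.0104201558610311	0.0104166666666667
T[T>C]C	0.000516528925619835	0.0104952967403705	0.0104166666666667
T[T>C]G	0.000516528925619835	0.0107104343136295	0.0104166666666667
T[T>C]T	0.000516528925619835	0.0110611854799542	0.0104166666666667
A[T>G]A	0.000516528925619835	0.00577020210889288	0.0104166666666667
A[T>G]C	0.000516528925619835	0.0060691635870907	0.0104166666666667
A[T>G]G	0.000516528925619835	0.00642138628914078	0.0104166666666667
A[T>G]T	0.000516528925619835	0.00681969421318196	0.0104166666666667
C[T>G]A	0.000516528925619835	0.00725597244104573	0.0104166666666667
C[T>G]C	0.000516528925619835	0.00772133246737198	0.0104166666666667
C[T>G]G	0.000516528925619835	0.00820629328938721	0.0104166666666667
C[T>G]T	0.000516528925619835	0.0087009745679165	0.0104166666666667
G[T>G]A	0.000516528925619835	0.00919529792426721	0.0104166666666667
G[T>G]C	0.000516528925619835	0.00967919227186677	0.0104166666666667
G[T>G]G	0.000516528925619835	0.0101427989993345	0.0104166666666667
G[T>G]T	0.000516528925619835	0.0105766728246944	0.0104166666666667
T[T>G]A	0.000516528925619835	0.0109719742286308	0.0104166666666667
T[T>G]C	0.000516528925619835	0.0113206495462495	0.0104166666666667
T[T>G]G	0.000516528925619835	0.0116155950482521	0.0104166666666667
T[T>G]T	0.000516528925619835	0.0118508016686158	0.0104166666666667
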