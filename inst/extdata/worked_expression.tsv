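gene_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010	S0011	S0012	S0013	S0014	S0015	S0016	S0017	S0018	S0019	S0020	S0021	S0022	S0023	S0024	S0025	S0026	S0027	S0028	S0029	S0030
G0001	-0.239427	2.272071	1.881505	-1.483377	1.493438	0.873782	0.188615	0.608351	0.783243	1.355049	-0.205044	-1.212462	2.882528	1.646672	2.680045	3.614249	0.217201	0.241069	1.354315	1.031544	0.372049	0.25433	1.647668	-0.491201	0.744788	1.55612	-0.600093	-0.609602	1.794724	0.269981
G0002	-1.040998	1.375814	1.14594	0.851329	0.756258	2.601068	0.285404	-1.878353	1.548106	2.028773	0.486881	-1.452166	-0.616465	-0.557513	0.43056	2.590856	1.500866	-1.458277	1.239949	-0.899455	0.252655	-0.243744	1.159198	0.179603	0.491127	0.179711	1.255995	-1.940584	1.892773	1.407851
G0003	-0.598003	2.610804	2.098855	1.688877	0.585974	2.861481	-0.300294	-0.785029	0.826855	1.890651	-0.618234	-0.847937	0.946305	0.367246	1.982485	3.685692	-0.296184	-0.972556	0.322718	0.039117	1.132611	0.633875	-0.143201	0.744936	-0.8829	-1.174938	0.052597	0.567322	0.499188	-0.414669
G0004	-0.182764	2.084858	2.024703	2.577091	0.039639	2.851863	-2.535696	0.419791	1.522936	1.839404	-1.297497	-0.699957	1.848886	0.360826	1.290318	1.389036	-1.68024	-1.002985	0.461184	-0.341628	2.207717	-0.254574	0.330401	0.592851	0.138899	1.417578	0.727181	-1.205179	1.174304	0.202808
G0005	-0.567188	1.53761	-0.049211	-0.85931	0.036136	-1.277638	-0.738137	-0.172001	0.641391	2.149026	0.423489	-0.517004	0.264707	-0.266597	1.272371	1.707005	-1.603487	1.228537	-0.394979	2.6632	1.114297	-1.902087	0.500405	-0.903239	-1.148493	-2.349353	1.560187	0.587604	-1.008317	0.274669
G0006	0.222732	1.217187	-1.656234	-1.455319	-0.599472	1.869432	1.281182	0.675836	0.263562	-0.780412	0.368072	0.408024	0.142264	-1.4755	0.284954	-0.456051	0.270584	0.167272	0.497431	0.190846	1.904749	-1.955066	-1.400073	1.311961	1.981764	-2.089818	0.051495	-0.385275	-0.073987	2.022942
G0007	-1.371647	-1.207927	0.380751	-1.010285	0.090214	0.836344	1.029604	2.787417	0.803819	1.190387	1.249962	2.543473	0.055661	-0.479194	-0.32514	0.449918	1.615123	0.680563	-0.333654	-1.936146	1.285473	0.59373	1.108038	-1.875085	0.91824	-3.753151	0.862597	-0.485299	-0.648396	1.264626
G0008	-1.323823	0.239416	0.234199	-1.358519	-0.659819	-0.207246	0.025593	-0.490556	1.314393	0.07649	-1.589866	-0.734727	0.958272	0.17875	0.670281	-0.170435	1.056399	-1.148041	-0.271401	-1.333488	-0.102209	-0.02062	-1.28685	0.611788	1.803084	0.09602	-0.003432	0.058532	-0.555019	-0.472906
G0009	-0.193792	-0.130337	-1.156304	-0.950207	-1.083957	0.523079	-2.483521	-1.785376	-0.924946	-0.790289	0.179934	0.236447	1.757868	1.000081	0.384492	-0.149582	-1.83237	-0.124701	-0.525258	-0.359372	0.603919	-0.518261	-0.13399	-0.763711	1.718945	-0.484121	-1.725803	-0.268299	1.191326	-0.096153
G0010	-1.947023	0.680331	-1.914586	-0.489841	0.824783	-1.151914	0.277376	0.601519	0.287962	-0.023847	1.445977	1.000353	1.048059	-2.385914	0.067266	0.675076	-0.394356	0.973339	1.531763	-2.630608	1.898455	-0.258312	0.057245	-2.169474	1.080558	-0.272924	-0.191727	-0.266843	0.288923	-0.145381
G0011	-0.126657	-0.358413	0.432684	-0.948744	-1.478868	-0.717075	0.168055	-0.526634	-0.026082	-0.749773	1.015086	1.796366	-0.201371	-0.973854	1.577002	-1.259601	-0.117626	0.517732	0.559577	-1.764419	-2.06287	-0.882543	-0.025376	-2.696363	-0.215545	0.907143	0.4113	-0.593854	0.461087	-0.093292
G0012	-1.637504	0.707984	-0.117363	2.28945	-0.259152	0.428132	-0.359893	0.607004	-0.71404	-1.922064	-0.541641	0.256446	-0.823429	-0.582845	-0.972274	-0.206694	-1.566703	0.580922	-0.968339	-1.081831	-0.176834	-0.368468	0.139401	-0.58537	-0.106702	0.02038	0.182621	-0.929087	2.449486	-0.238812
G0013	1.081211	-1.873691	0.480337	0.360252	-2.408686	-0.819414	-0.248284	-0.651422	-0.989479	-2.268627	1.02344	1.407075	-0.023211	-1.934571	-0.913675	0.215227	0.58596	0.623997	-1.684372	-0.307938	-0.658395	-1.142433	0.585965	1.392985	-0.911758	-1.043225	-0.480724	0.897097	0.661536	0.133073
G0014	-0.359604	1.560824	-1.066277	0.168369	-1.67322	0.569101	0.025869	2.373018	-0.585852	-1.343781	-0.581015	-1.476631	-1.071096	-1.021948	-1.988825	-0.359247	-2.569905	1.906968	-0.643326	1.278893	0.37618	-2.194137	-0.138759	-0.557173	0.491184	0.626127	-1.524535	-0.522393	0.182864	-0.892208
G0015	-0.553804	0.736143	-0.731445	0.748097	-1.476455	1.676788	-0.802246	0.037257	0.631688	-0.507948	-0.162486	1.614281	-0.800816	-1.048766	-0.483415	0.14888	0.03472	0.081161	1.686509	-0.234206	0.248562	-0.430728	-0.261082	0.300235	0.711645	1.365716	0.339563	-1.092647	1.467215	-0.611211
G0016	-0.630915	-1.032358	1.438194	-0.821089	-0.372904	-1.397226	2.032029	-0.869255	-0.278047	0.068983	1.887403	-0.171307	1.05142	-0.432071	0.340466	-0.379329	-0.4826	0.438039	1.610917	0.488983	1.225294	0.984101	0.214364	0.647503	-0.593363	-1.998541	-1.928795	-0.754287	-1.035815	0.715125
G0017	0.599575	-2.330589	0.756194	-0.990592	1.366768	-1.101793	1.192444	-0.558181	-0.646612	-1.244585	0.409723	0.242822	0.39692	-1.898336	-2.621278	1.557896	-0.582542	0.660513	-2.150197	0.261995	2.417052	1.816154	-0.379606	-0.845782	-0.708741	-1.105309	-2.264162	-1.047374	0.824351	-0.125841
G0018	-0.192945	-0.238573	0.938906	0.618283	-0.004703	-0.316788	-0.52062	0.470644	0.301692	-1.164234	1.528415	-0.590166	0.195923	0.503917	-0.799956	0.65374	-0.375026	-1.427405	-0.787303	-0.378635	-0.601253	-0.058569	1.591449	0.762794	0.582167	-0.790565	-0.417411	-2.439224	-0.926229	-0.680525
G0019	0.073845	-0.398388	2.167647	-1.075535	0.262287	-1.380949	2.103626	-0.294579	-1.098439	-0.625954	0.408641	0.653122	-0.300701	-0.341425	-1.731541	2.905417	0.223416	-0.116828	1.102884	1.688799	1.834959	-0.141845	-2.11621	0.161785	-0.844684	-1.788003	-2.24515	-0.537376	-1.164709	0.94493
G0020	1.895013	-0.887937	0.48124	-2.142107	-0.92431	-0.746636	1.92651	-2.017536	1.184149	-0.384667	-0.876494	2.304592	0.88594	1.810989	0.892047	-0.855526	0.304948	-0.249309	-0.46864	-0.769911	-0.655291	0.901807	1.081041	0.015432	-0.380796	0.195786	-0.767975	-0.079265	-1.716682	-0.012738
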