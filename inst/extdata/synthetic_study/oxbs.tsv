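probe_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010
probe_00001	0.36036036036036	0.383177570093458	0.574712643678161	0.450549450549451	0.475247524752475	0.46551724137931	0.493150684931507	0.440559440559441	0.428571428571429	0.496732026143791
probe_00002	0.327586206896552	0.548148148148148	0.14018691588785	0.272727272727273	0.315315315315315	0.299212598425197	0.575	0.303370786516854	0.447058823529412	0.36283185840708
probe_00003	0.894230769230769	1	0.770642201834862	0.869918699186992	0.521739130434783	0.617021276595745	0.526315789473684	0.573333333333333	0.914285714285714	0.51685393258427
probe_00004	0.457627118644068	0.666666666666667	0.6	0.583333333333333	0.491071428571429	0.439393939393939	0.418604651162791	0.450704225352113	0.569105691056911	0.560747663551402
probe_00005	0.398550724637681	0.489795918367347	0.51	0.461538461538462	0.742424242424242	0.246376811594203	0.0379746835443038	0.3	0.28735632183908	0.311475409836066
probe_00006	0.2	0.301204819277108	0.310344827586207	0.34375	0.283185840707965	0.266129032258065	0.19047619047619	0	0.28125	0.1875
probe_00007	0.384615384615385	0.36734693877551	0.123287671232877	0.33695652173913	0.53968253968254	0.217391304347826	0.201342281879195	0.471698113207547	0.240506329113924	0.458333333333333
probe_00008	0.488636363636364	0.5375	0.46031746031746	0.515789473684211	0.49438202247191	0.352517985611511	0.507246376811594	0.341666666666667	0.260869565217391	0.436781609195402
probe_00009	0.404255319148936	0.414473684210526	0.166666666666667	0.453333333333333	0.585106382978723	0.474137931034483	0.366071428571429	0.601941747572815	0.541666666666667	0.457364341085271
probe_00010	0.494845360824742	0.637037037037037	0.682692307692308	0.506329113924051	0.431034482758621	0.538461538461538	0.465116279069767	0.488095238095238	0.370967741935484	0.578512396694215
probe_00011	0.38	0.247933884297521	0.489795918367347	0.573170731707317	0.336206896551724	0.358974358974359	0.174603174603175	0.408450704225352	0.349206349206349	0.373134328358209
probe_00012	0.397727272727273	0.464516129032258	0.376623376623377	0.513274336283186	0.430769230769231	0.359649122807018	0.474226804123711	0.563636363636364	0.277777777777778	0.615384615384615
probe_00013	0.660194174757282	0.514705882352941	0.435643564356436	0.461538461538462	0.51063829787234	0.63013698630137	0.364864864864865	0.508771929824561	0.604166666666667	0.464285714285714
probe_00014	0.30379746835443	0.434210526315789	0.365384615384615	0.291044776119403	0.370860927152318	0.459677419354839	0.438356164383562	0.446808510638298	0.458715596330275	0.148514851485149
probe_00015	0.341880341880342	0.671428571428571	0.703448275862069	0.737704918032787	0.611111111111111	0.615384615384615	0.495934959349593	0.517241379310345	0.49645390070922	0.2734375
probe_00016	0.40952380952381	0.478991596638655	0.225225225225225	0.634328358208955	0.311827956989247	0.238095238095238	0.309859154929577	0.264705882352941	0.289473684210526	0.26027397260274
probe_00017	0.236220472440945	0.457943925233645	0.182481751824818	0.36231884057971	0.585106382978723	0.366197183098592	0.182926829268293	0.207920792079208	0.488095238095238	0.274336283185841
probe_00018	0.49438202247191	0.467532467532468	0.740384615384615	0.529411764705882	0.440298507462687	0.692307692307692	0.263157894736842	0.53	0.568421052631579	0.580882352941177
probe_00019	0.382608695652174	0.552	0.385964912280702	0.570175438596491	0.460674157303371	0.44	0.4375	0.378048780487805	0.323529411764706	0.675213675213675
probe_00020	0.364864864864865	0.504761904761905	0.205128205128205	0.260869565217391	0.318840579710145	0.509316770186335	0.366666666666667	0.41025641025641	0.397727272727273	0.455555555555556
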