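probe_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010
probe_00001	0.543103448275862	0.75	0.612903225806452	0.69620253164557	0.763358778625954	0.616883116883117	0.869565217391304	0.686274509803922	0.843137254901961	0.770114942528736
probe_00002	0.793814432989691	0.790322580645161	0.431192660550459	0.45679012345679	0.386363636363636	0.5	0.942857142857143	0.4375	0.379310344827586	0.674157303370786
probe_00003	0.894230769230769	1	0.770642201834862	0.869918699186992	0.521739130434783	0.617021276595745	0.526315789473684	0.573333333333333	0.914285714285714	0.51685393258427
probe_00004	0.746478873239437	NA	0.873684210526316	0.863636363636364	0.6875	0.640776699029126	0.64	0.773809523809524	0.852941176470588	0.75
probe_00005	0.491071428571429	0.974358974358974	0.723684210526316	0.716216216216216	0.842465753424658	0.647058823529412	0.261904761904762	0.736111111111111	0.705882352941177	0.466019417475728
probe_00006	0.418181818181818	0.533333333333333	0.641791044776119	0.6	0.302469135802469	0.604395604395604	0.574626865671642	0.585365853658537	0.623655913978495	0.746153846153846
probe_00007	0.458333333333333	0.677777777777778	0.226666666666667	0.567796610169492	0.669230769230769	0.458333333333333	0.265822784810127	0.634920634920635	0.49438202247191	0.72972972972973
probe_00008	0.793893129770992	0.701754385964912	0.619047619047619	0.551724137931034	0.67741935483871	0.592233009708738	0.794117647058823	0.604651162790698	0.372549019607843	0.743589743589744
probe_00009	0.666666666666667	0.62	0.477611940298507	0.782051282051282	1	0.594059405940594	0.982142857142857	0.82051282051282	0.720930232558139	1
probe_00010	0.877777777777778	1	0.927536231884058	0.520408163265306	0.545454545454545	0.729411764705882	0.891304347826087	0.729166666666667	0.633663366336634	0.639705882352941
probe_00011	0.791044776119403	0.691780821917808	0.716312056737589	0.595959595959596	0.675	0.605769230769231	0.426966292134831	0.5	0.47787610619469	0.455882352941176
probe_00012	0.590909090909091	0.590909090909091	0.568627450980392	0.879310344827586	0.686440677966102	0.6328125	0.642424242424242	0.62962962962963	0.398058252427184	0.780487804878049
probe_00013	0.80952380952381	0.990566037735849	0.741935483870968	0.770114942528736	0.752688172043011	0.851239669421488	0.595238095238095	0.861538461538462	0.740740740740741	0.841584158415842
probe_00014	0.565891472868217	0.536363636363636	0.493975903614458	0.587837837837838	0.417910447761194	0.964285714285714	0.864583333333333	0.722222222222222	0.657142857142857	0.305084745762712
probe_00015	0.495652173913044	0.910112359550562	1	1	0.825	0.673684210526316	1	0.873563218390805	0.912621359223301	0.485981308411215
probe_00016	0.631067961165049	0.666666666666667	0.345238095238095	0.869230769230769	0.551020408163265	0.461538461538462	0.602272727272727	0.456310679611651	0.585106382978723	0.474747474747475
probe_00017	0.485981308411215	0.753246753246753	0.391666666666667	0.619718309859155	0.964285714285714	0.587786259541985	0.570422535211268	0.435185185185185	0.936507936507937	0.525862068965517
probe_00018	0.883928571428571	0.552941176470588	1	0.763157894736842	0.645669291338583	1	0.658119658119658	0.895522388059702	0.825396825396825	0.82312925170068
probe_00019	0.616822429906542	0.772727272727273	0.5546875	0.658333333333333	0.529411764705882	0.704761904761905	0.555555555555556	0.688888888888889	0.6796875	0.725806451612903
probe_00020	0.570247933884298	0.886075949367089	0.6	0.478723404255319	0.54	0.695652173913043	0.532467532467532	0.631578947368421	0.699248120300752	0.441558441558442
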