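compound_id,class,solvent,C1,C2,C3,C4,C5,C6,C7,C9,H_CHO_1,H_CHO_2,H_OH_1,H_OH_2
syn-01-001,pyrano-diformyl,CDCl3,160.0253029130402,104.82563425763222,162.363726112584,106.14972190293454,160.66272239011133,109.60786309143549,192.8155615675758,191.33487632060857,9.657392806215734,10.243199189862423,12.81643868845633,13.177525913218933
syn-01-002,pyrano-diformyl,CDCl3,159.72257832482657,104.33480264866519,163.7051842604119,106.35757951351235,161.2278730067323,111.4342617648557,191.74377939809463,190.21531862803286,11.471312310914893,10.477988241534115,13.14701996696395,13.757177872447308
syn-01-003,pyrano-diformyl,CDCl3,159.67292611414214,105.54255429623818,163.03025155665858,105.82961904432987,161.38567806688187,110.32428420004892,192.16260295368525,191.11070434359976,9.324620523853593,,11.818705204094623,13.283018598009715
syn-01-004,pyrano-diformyl,CDCl3,159.66203802935314,104.8397655130273,163.03513754933823,104.81413324732813,161.06959435125373,109.71060947023074,191.55682868570506,191.18677483439438,10.401723493703821,9.884857408811813,12.220526521033728,12.689257719292236
syn-01-005,pyrano-diformyl,CDCl3,159.69161703241454,103.8631860515038,162.9810493336201,106.16227456693083,161.27052808456065,110.80470397719466,191.9276429533942,190.12223992978318,9.7794111384804,9.835387888999525,12.738082461805691,13.20243807883031
syn-01-006,pyrano-diformyl,CDCl3,159.86236887371078,105.27184527840384,163.640552189542,106.41788967051964,161.23287711868616,109.43079660785885,192.55093014964498,191.54495965748896,10.915767996391683,,13.226490512393722,12.996016109914208
syn-01-007,pyrano-diformyl,CDCl3,160.31803502431438,105.16608739181135,162.513243477988,106.81755229764566,161.18232329942845,110.72410584946184,192.31309075345285,191.0030946003487,10.751422872118436,10.600922008896186,12.660091145240726,13.213871785124894
syn-01-008,pyrano-diformyl,CDCl3,160.8580555146749,104.51696252198394,163.1789005002604,106.08548828328767,161.42005626341393,109.9443311386742,192.4311175522479,190.46204580592592,9.737262825954605,10.864870719033924,12.642842468698545,13.581134813756053
syn-01-009,pyrano-diformyl,CDCl3,160.45047442112238,105.42304610914861,162.0915742571753,105.88044996983125,161.07586547519784,110.44019608643853,191.8814534491317,190.77177517254987,9.68074923893706,10.76864228576052,12.138670521304713,
syn-01-010,pyrano-diformyl,CDCl3,159.35777021115928,104.69988555652883,162.47962188363428,105.27105539871226,161.74421656700318,110.15080344791623,192.57122229000433,190.54534089980908,10.576948930278512,10.156911440432282,13.279333044389508,13.000063700241062
syn-01-011,pyrano-diformyl,CDCl3,159.62321143453676,104.14229932801794,162.542250601836,105.76575154267829,160.72927201604872,109.44345420030218,191.7555953078485,191.8370316941951,10.962160853825749,9.747255675146496,12.69675159574063,13.0705022243109
syn-01-012,pyrano-diformyl,CDCl3,159.44180973052187,105.68597194268861,163.16980605773273,105.52010719117588,161.68939072499685,109.88000869961752,192.50837822261636,190.7673628853955,9.950512702129638,9.584185567867785,12.995427874528582,13.246304424200051
syn-01-013,pyrano-diformyl,CDCl3,161.35678787697415,105.33691978529801,163.63892332271644,106.36126403664922,160.99559122028577,109.88710411914953,191.39998336922707,191.2757763140062,9.724382182137463,10.976271880436666,12.588688987158887,13.60465305569962
syn-01-014,pyrano-diformyl,CDCl3,159.22405766795725,105.23430578874797,162.92751138454875,106.64778414106374,161.7147077731084,110.23336234683616,192.04004689569032,191.670568295934,10.062126371747924,10.344269519002678,12.923783910380962,12.585404255797691
syn-01-015,pyrano-diformyl,CDCl3,159.95144744415376,105.19639061510468,163.4555934470468,105.87474866930246,161.07516882846957,109.41679837964043,192.49371346856387,190.16614936959346,9.851918871706594,10.107827793960677,13.350656491681766,12.993387189745661
syn-02-001,oxepine-diformyl,CDCl3,165.81108415499597,105.03510570848975,162.5922867162771,106.34740210637624,161.05575090350968,109.94780493943446,198.26085067293735,197.0026372505674,9.82859010983449,9.71944990644145,12.699420223162043,13.823619407557416
syn-02-002,oxepine-diformyl,CDCl3,166.44392930748612,104.06169181534199,163.15932176107768,106.64229470792435,162.13966843523676,109.65560734076821,198.48569271327597,197.36017197752383,10.051954959711638,9.751599282853835,12.559242440772529,13.273250296563218
syn-02-003,oxepine-diformyl,CDCl3,165.51543803751292,104.54793455782665,163.9111529454865,105.33636730066057,160.13962962453215,109.99003373032379,197.90520385100265,197.7617853698064,9.708081852834821,10.597332813349025,12.813980509427386,13.521129001855453
syn-02-004,oxepine-diformyl,CDCl3,166.95387023191134,104.86734834195144,162.6050690643545,105.3395492477083,160.64201024759396,109.98877946457628,197.95505261075127,196.17565671184624,10.768502557510047,9.632157436076147,12.069802378185853,13.864278729365012
syn-02-005,oxepine-diformyl,CDCl3,165.97705179654966,104.76866773461626,163.76057187215454,106.0408692946209,161.21850434985873,109.1942227866982,197.6781219407634,196.33200703096875,10.686568467063283,10.287961114842664,12.689259774764768,12.875951162448034
syn-02-006,oxepine-diformyl,CDCl3,165.33767854491984,104.04746653903291,162.73421802627024,105.74541847339513,161.34686111941477,111.16708101171979,197.68837189031564,196.78167515337594,10.100856141367222,,12.704228085953917,
syn-02-007,oxepine-diformyl,CDCl3,165.98417678078275,104.12628022187154,163.01689911024116,105.88015095402349,160.6617510361057,109.45505100562701,198.0028949817836,197.44722405684217,10.150874484612851,,12.169607770459821,13.909576019522872
syn-02-008,oxepine-diformyl,CDCl3,166.6378760358551,104.94009052482811,162.98235584136341,106.0079173408248,161.44002132799687,108.4841835610422,197.81175403297104,196.72551603014622,9.561621423902515,,13.374880249062633,12.660523443492256
syn-02-009,oxepine-diformyl,CDCl3,165.73379968026953,104.96271832177881,163.23655505483376,105.6296282626645,161.75087598130918,110.27301712317924,198.81107287362425,197.07228204699206,9.851435892636367,,12.724082677654438,13.388783818826347
syn-02-010,oxepine-diformyl,CDCl3,166.06360188630472,104.90688621384493,163.21259754310202,105.72030487436983,161.65739403676116,109.69127010775298,197.44619150484468,196.99916609178848,10.065749242708494,10.076093578538144,12.850945143824303,13.379164096128395
syn-02-011,oxepine-diformyl,CDCl3,166.22845605631437,104.84004630655632,162.946270206499,105.78491484726327,160.4235401353482,109.98060936258328,197.80887471679955,196.43001710728234,9.999360500974124,10.493828627729107,12.21474574402626,12.908025396731329
syn-02-012,oxepine-diformyl,CDCl3,165.66627503835522,105.11611022513583,162.9406478324714,105.74818460829425,160.7994859132406,109.91856421054665,197.7186517478202,196.2068196655273,9.98237943273344,10.041741161014997,13.046824368871835,12.937955450642754
syn-02-013,oxepine-diformyl,CDCl3,165.75556270535702,105.70372018339918,162.78362122046613,106.93847144644656,160.8031154476966,109.79557649258273,197.98374622530795,197.5181179213289,10.578085345971928,9.267936405949357,11.983475558810479,13.113300153245664
syn-02-014,oxepine-diformyl,CDCl3,166.02375285214328,104.60493337912207,163.6530560165323,105.60313572579614,161.22545163478117,110.01190516643484,197.89940818838429,197.81676302044772,10.602306761850052,,12.016236398042414,13.207716727646003
syn-02-015,oxepine-diformyl,CDCl3,165.5583723956138,104.59681269644462,163.1423611333081,106.48065930199493,161.0085880827859,109.99919718677434,197.36165150505164,196.51502537186627,10.147286313234352,10.347902079646516,12.449449250474242,13.448468030763419
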