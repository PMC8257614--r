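"stem_id","kind","theta_deg","H_mm","prickle_height_mm"
"synthetic-seed1","leaf",76.3713076617569,38.8984323641143,
"synthetic-seed1","prickle",44.2959212722671,52.9880813199375,
"synthetic-seed1","leaf",207.606769554334,67.6860265586963,
"synthetic-seed1","prickle",80.9491586440851,74.6976823720013,
"synthetic-seed1","leaf",346.943202796554,80.5390276869213,
"synthetic-seed1","prickle",246.508686732243,83.7087465008284,
"synthetic-seed1","prickle",52.8809579209305,103.588244648735,
"synthetic-seed1","leaf",116.086916672454,126.788336868352,
"synthetic-seed1","prickle",20.4557542795778,148.678622627001,
"synthetic-seed1","leaf",269.539724693832,161.3390007782,
"synthetic-seed1","prickle",81.3471911607865,167.257611053074,
"synthetic-seed1","prickle",164.214345615977,169.345397507937,
"synthetic-seed1","prickle",13.0292712780766,171.616925771081,
"synthetic-seed1","prickle",91.8064118249425,175.16394350198,
"synthetic-seed1","prickle",178.028889795535,187.428201235581,
"synthetic-seed1","prickle",215.601417146277,191.582020043718,
"synthetic-seed1","leaf",50.3348024119854,196.177098147211,
"synthetic-seed1","prickle",173.540325361821,197.689176847427,
"synthetic-seed1","prickle",241.01305868624,199.015885046502,
"synthetic-seed1","prickle",94.5069357749754,215.304335966136,
"synthetic-seed1","leaf",179.630118570805,240.615460254064,
"synthetic-seed1","prickle",293.775748446477,258.217173270647,
"synthetic-seed1","prickle",0.606050559655387,268.435481823815,
"synthetic-seed1","prickle",162.764496084216,268.876722652819,
"synthetic-seed1","leaf",322.00440909509,283.827672205044,
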