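worker_role,facility,finger,hp007_mSv
nurse,PET-I,thumb,0.044
nurse,PET-I,index,0.160
nurse,PET-I,middle,0.106
nurse,PET-I,ring,0.002
nurse,PET-I,small,0.064
nurse,PET-II,thumb,0.052
nurse,PET-II,index,0.269
nurse,PET-II,middle,0.119
nurse,PET-II,ring,0.077
nurse,PET-II,small,0.079
nurse,PET-II,thumb,0.078
nurse,PET-II,index,0.188
nurse,PET-II,middle,0.027
nurse,PET-II,ring,0.050
nurse,PET-II,small,0.060
chemist,RPC-I,thumb,0.015
chemist,RPC-I,index,0.153
chemist,RPC-I,middle,0.130
chemist,RPC-I,ring,0.163
chemist,RPC-I,small,0.056
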