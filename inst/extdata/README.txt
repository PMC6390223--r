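Place an export of Zenodo record 2247283 here as zenodo_grasps.csv
(columns: participant, material, orientation_deg, repetition,
thumb_x, thumb_y, thumb_z, index_x, index_y, index_z; cm)
to enable the deposited-data replication test.
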