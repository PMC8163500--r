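# Report schema: table_name: required, columns
itpc_spectra: participant, condition, freq_hz, z, seed
foi_tests: condition, foi_hz, t, df, p, cohen_d, seed
foi_condition_tests: foi_hz, observed_t, p, n_perm, seed
channel_group_1hz: group, condition, mean_z_1hz, observed_t, p, seed
roi_global: hemisphere, foi_hz, global_stat, global_p, n_perm, seed
roi_detail: hemisphere, roi, t, p_uncorrected, suprathreshold, seed
trf_hyperparams: tolerance, sparseness, score, selected, seed
trf_predictive_power: participant, mean_r, seed
trf_power_null: observed_r, p, n_perm, seed
trf_kernels: condition, channel, lag_ms, weight, seed
trf_cluster_scalp: cluster, mass, corrected_p, n_points, units, t_start_ms, t_end_ms, seed
trf_cluster_roi: cluster, mass, corrected_p, n_points, units, t_start_ms, t_end_ms, seed
behavior_accuracy: participant_id, condition, accuracy, seed
behavior_stats: test, t, df, p, seed
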