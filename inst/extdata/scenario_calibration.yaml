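# Calibration targets for the synthetic cohort generator.
#
# Per scenario: the fractionation of the whole-breast course and the boost,
# the default cohort size, per-organ mean-dose targets (mean and SD of the
# patient-to-patient distribution of the summed-plan organ Dmean, in Gy) with
# the risk-model routing, the share of the organ dose contributed by the
# boost course, and the full-course TLD organ-dose targets per phantom
# breast size (mean, SD in Gy). Targets transcribe published cohort
# statistics for the four breast treatment scenarios; generator mechanics
# (mixture components, noise model) live in code, these numbers are data.
generator:
  voxel_count: 5000
  voxel_volume_cm3: 0.008
  in_field_rel_width: 0.05     # in-field voxels ~ prescription +/- 5%
  penumbra_lo: 0.2             # penumbra uniform between these fractions
  penumbra_hi: 0.8             #   of the prescription
  organ_mixture:
    heart:        {penumbra_fraction: 0.04, out_of_field_mean_gy: 0.8}
    lung_ipsi:    {penumbra_fraction: 0.12, out_of_field_mean_gy: 0.7}
  tld_noise_cv: 0.10
  tld_background_gy: 0.002
  tld_n_readings: 5
  tld_n_background: 3
  tld_outlier_factor: 8

scenarios:
  imrt_brachy:
    label: "IMRT + brachytherapy"
    wbi: {n_fractions: 25, dose_per_fraction: 2.0}
    boost: {n_fractions: 2, dose_per_fraction: 6.0, type: brachy}
    cohort_size: 10
    boost_oar_share: 0.03
    organs:
      heart:         {dmean_mean: 4.5,  dmean_sd: 1.3,  route: in_field}
      lung_ipsi:     {dmean_mean: 9.9,  dmean_sd: 2.3,  route: in_field}
      lung_contra:   {dmean_mean: 0.5,  dmean_sd: 0.10, route: out_of_field}
      breast_contra: {dmean_mean: 1.4,  dmean_sd: 0.80, route: out_of_field}
    tld:
      small: {heart: [1.1, 0.3],  lung_ipsi: [3.3, 2.4],
              lung_contra: [0.4, 0.1], breast_contra: [1.6, 0.6]}
      large: {heart: [3.1, 2.8],  lung_ipsi: [18.8, 13.9],
              lung_contra: [0.6, 0.1], breast_contra: [1.2, 1.0]}
  imrt_sib:
    label: "IMRT + SiB"
    wbi: {n_fractions: 28, dose_per_fraction: 1.8}
    boost: {n_fractions: 28, dose_per_fraction: 2.14, type: sib}
    cohort_size: 10
    boost_oar_share: 0.0
    organs:
      heart:         {dmean_mean: 4.4,  dmean_sd: 1.0,  route: in_field}
      lung_ipsi:     {dmean_mean: 10.8, dmean_sd: 1.8,  route: in_field}
      lung_contra:   {dmean_mean: 0.45, dmean_sd: 0.15, route: out_of_field}
      breast_contra: {dmean_mean: 1.35, dmean_sd: 0.75, route: out_of_field}
    tld:
      small: {heart: [1.7, 0.4],  lung_ipsi: [2.3, 1.4],
              lung_contra: [0.5, 0.2], breast_contra: [1.7, 0.8]}
      large: {heart: [1.2, 0.4],  lung_ipsi: [10.4, 18.3],
              lung_contra: [0.4, 0.1], breast_contra: [1.0, 0.7]}
  3dcrt_brachy:
    label: "3D-CRT + brachytherapy"
    wbi: {n_fractions: 25, dose_per_fraction: 2.0}
    boost: {n_fractions: 2, dose_per_fraction: 6.0, type: brachy}
    cohort_size: 8
    boost_oar_share: 0.03
    organs:
      heart:         {dmean_mean: 3.3,  dmean_sd: 1.6,  route: in_field}
      lung_ipsi:     {dmean_mean: 7.9,  dmean_sd: 1.1,  route: in_field}
      lung_contra:   {dmean_mean: 0.3,  dmean_sd: 0.10, route: out_of_field}
      breast_contra: {dmean_mean: 1.35, dmean_sd: 0.65, route: out_of_field}
    tld:
      small: {heart: [0.6, 0.2],  lung_ipsi: [1.0, 0.7],
              lung_contra: [0.2, 0.1], breast_contra: [1.7, 0.6]}
      large: {heart: [1.4, 0.5],  lung_ipsi: [12.8, 17.2],
              lung_contra: [0.4, 0.1], breast_contra: [1.0, 0.7]}
  3dcrt_seq:
    label: "3D-CRT + sequential boost"
    wbi: {n_fractions: 25, dose_per_fraction: 2.0}
    boost: {n_fractions: 5, dose_per_fraction: 2.0, type: teletherapy}
    cohort_size: 10
    boost_oar_share: 0.17
    organs:
      heart:         {dmean_mean: 4.8,  dmean_sd: 2.1,  route: in_field}
      lung_ipsi:     {dmean_mean: 8.7,  dmean_sd: 2.2,  route: in_field}
      lung_contra:   {dmean_mean: 0.45, dmean_sd: 0.25, route: out_of_field}
      breast_contra: {dmean_mean: 1.8,  dmean_sd: 1.1,  route: out_of_field}
    tld:
      small: {heart: [1.9, 0.7],  lung_ipsi: [1.5, 1.5],
              lung_contra: [0.5, 0.4], breast_contra: [2.4, 1.1]}
      large: {heart: [1.3, 0.5],  lung_ipsi: [12.7, 17.1],
              lung_contra: [0.4, 0.1], breast_contra: [1.2, 1.1]}
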