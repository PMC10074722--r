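{
  "description": "Canonical column schema for the 43 traditional per-residue features; map NACCESS/DSSP/PSAIA/HBPLUS outputs onto these names.",
  "delimiter": "comma or tab, auto-detected",
  "decimal": ".",
  "encoding": "UTF-8",
  "metadata_columns": ["pdb_id", "chain", "position", "wt_residue", "ddg"],
  "label_column": "label",
  "blocks": {
    "asa_monomer": ["asa_all_mono", "asa_nonpolar_mono", "asa_polar_mono", "asa_side_mono", "rsa_all_mono", "rsa_nonpolar_mono", "rsa_polar_mono", "rsa_side_mono"],
    "asa_complex": ["asa_all_comp", "asa_nonpolar_comp", "asa_polar_comp", "asa_side_comp", "rsa_all_comp", "rsa_nonpolar_comp", "rsa_polar_comp", "rsa_side_comp"],
    "asa_relative_change": ["asa_all_delta", "asa_nonpolar_delta", "asa_polar_delta", "asa_side_delta", "rsa_all_delta", "rsa_nonpolar_delta", "rsa_polar_delta", "rsa_side_delta"],
    "secondary_structure": ["dssp_tco", "dssp_kappa", "dssp_alpha", "dssp_phi", "dssp_psi", "dssp_water"],
    "depth_protrusion": ["dpx_mean_bound", "dpx_mean_unbound", "dpx_sd_bound", "dpx_sd_unbound", "cx_mean_bound", "cx_mean_unbound", "cx_sd_bound", "cx_sd_unbound", "dpx_mean_delta", "dpx_sd_delta", "cx_mean_delta", "cx_sd_delta"],
    "hydrogen_bond": "hbond_count"
  },
  "column_order": ["asa_all_mono", "asa_nonpolar_mono", "asa_polar_mono", "asa_side_mono", "rsa_all_mono", "rsa_nonpolar_mono", "rsa_polar_mono", "rsa_side_mono", "asa_all_comp", "asa_nonpolar_comp", "asa_polar_comp", "asa_side_comp", "rsa_all_comp", "rsa_nonpolar_comp", "rsa_polar_comp", "rsa_side_comp", "asa_all_delta", "asa_nonpolar_delta", "asa_polar_delta", "asa_side_delta", "rsa_all_delta", "rsa_nonpolar_delta", "rsa_polar_delta", "rsa_side_delta", "dssp_tco", "dssp_kappa", "dssp_alpha", "dssp_phi", "dssp_psi", "dssp_water", "dpx_mean_bound", "dpx_mean_unbound", "dpx_sd_bound", "dpx_sd_unbound", "cx_mean_bound", "cx_mean_unbound", "cx_sd_bound", "cx_sd_unbound", "dpx_mean_delta", "dpx_sd_delta", "cx_mean_delta", "cx_sd_delta", "hbond_count"]
}
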