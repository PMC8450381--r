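{
  "grid": {
    "start_nm": 400,
    "stop_nm": 700,
    "step_nm": 10
  },
  "files": {
    "illuminant_d65.csv": "CIE standard illuminant D65 relative SPD",
    "camera_response_r.csv": "Gaussian red-channel response, peak 610 nm, FWHM 60 nm",
    "camera_response_g.csv": "Gaussian green-channel response, peak 540 nm, FWHM 60 nm",
    "camera_response_b.csv": "Gaussian blue-channel response, peak 460 nm, FWHM 60 nm",
    "extinction_hbo2.csv": "Oxyhemoglobin molar extinction, cm^-1/M, literature compilation",
    "extinction_hb.csv": "Deoxyhemoglobin molar extinction, cm^-1/M, literature compilation",
    "extinction_melanin.csv": "Eumelanin extinction shape, 6.6e10*lambda^-3.33",
    "mua_baseline_skin.csv": "Pigment-free cutaneous baseline absorption, cm^-1",
    "mus_epidermis.csv": "Epidermis scattering coefficient, cm^-1",
    "mus_dermis.csv": "Dermis scattering coefficient, cm^-1",
    "g_epidermis_dermis.csv": "Henyey-Greenstein anisotropy, epidermis and dermis",
    "mua_hypodermis.csv": "Subcutaneous fat absorption, cm^-1",
    "mus_hypodermis.csv": "Subcutaneous fat scattering, cm^-1",
    "g_hypodermis.csv": "Subcutaneous fat anisotropy"
  },
  "notes": "Camera curves are synthetic Gaussian stand-ins for an unpublished 2-CCD sensor; substitute measured curves via the camera_dir configuration hook."
}
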