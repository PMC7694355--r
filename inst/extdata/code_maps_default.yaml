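departure_status_admission_expected:
- ward_this_hospital
- procedure_room_this_campus
- transfer_other_campus
departure_status_no_admission:
- usual_residence
- left_before_treatment_complete
- died_in_ed
admission_type_ed_expected:
- emergency_this_hospital
admission_type_uncertain:
- waiting_list
- other_admission
- maternity
- statistical_admission
- other_emergency
separation_mode_transfer:
- statistical_separation
- transfer_other_hospital
separation_mode_no_transfer:
- discharge_home
- died_in_hospital
- left_against_advice
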