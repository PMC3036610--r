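column,type,unit,required
subject_id,character,,FALSE
group,factor,control|ms_only|t2dm_only|t2dm_ms,TRUE
ethnicity,factor,malay|chinese|indian,TRUE
age,numeric,years,TRUE
bmi,numeric,kg/m2,FALSE
waist,numeric,cm,FALSE
whr,numeric,ratio,FALSE
sbp,numeric,mmHg,FALSE
dbp,numeric,mmHg,FALSE
total_chol,numeric,mmol/L,FALSE
hdl,numeric,mmol/L,FALSE
ldl,numeric,mmol/L,FALSE
tg,numeric,mmol/L,FALSE
glucose,numeric,mmol/L,TRUE
hba1c,numeric,%,FALSE
insulin,numeric,uU/mL,TRUE
adiponectin,numeric,ug/mL,TRUE
resistin,numeric,ng/mL,TRUE
smoking,logical,,FALSE
hypertension,logical,,FALSE
family_history,logical,,FALSE
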