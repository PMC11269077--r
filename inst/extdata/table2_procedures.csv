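procedure,cases,deaths,unadjusted_pct,model_pct,risk_stratification,rachs_grade,rachs_grade_raw,stseacts_grade
ASD hybrid repair (off pump),87,0,0,0.46,1,2,2,2
ASD secundum repair,551,1,0.18,0.13,1,1,1,1
ASD secundum repair (patch),1338,1,0.07,0.14,1,1,1,1
AVSD repair - depression,391,3,0.77,0.42,1,3,3,3
AVSD repair - single patch,116,1,0.86,0.39,1,3,3,3
Aortic valvuloplasty,109,1,0.92,0.40,1,2,2,2
Coronary art. fistula repair,78,0,0,0.50,1,2,2,2
Cortraitriatum repair,70,0,0,0.50,1,3,3,2
Mitral valvuloplasty,461,7,1.52,0.85,1,3,3,2
PAPVD isolated repair,115,0,0,0.37,1,1,1,1
Pulm. Infundibulum resection (indirect),178,0,0,0.31,1,2,2,1
Subaortic fibromyectomy,155,0,0,0.32,1,3,3,1
Subaortic myectomy,80,1,1.25,0.52,1,3,3,1
Tricuspid valvuloplasty,540,3,0.56,0.77,1,3,3,2
VSD canal type repair,154,0,0,0.33,1,3,3,1
VSD membranous repair,7910,23,0.29,0.33,1,2,2,1
VSD subarterial repair,1641,1,0.06,0.12,1,2,2,1
Vascular ring repair,132,0,0,0.37,1,2,2,1
A-P window repair,31,1,3.23,0.79,2,2,2,2
A-V fistula repair,6,1,16.67,1.53,2,2,2,2
ASD common atrium repair,9,0,0,1.27,2,2,2,2
ASD repair - minimal invasive & CPB,29,0,0,0.81,2,2,2,2
ASD sinus venosus repair,38,0,0,0.67,2,1,1,2
Aortic valvotomy,56,0,0,0.61,2,2,2,2
Asc. aorta patch aortoplasty,184,6,3.26,1.97,2,2,2,2
Coarct repair - bypass or tubular graft,4,0,0,1.53,2,1,1,1
Coarct. repair - resection & E to S,377,10,2.65,1.64,2,2,1/2,2
Coarct. repair - patch aortoplasty,253,4,1.58,1.92,2,2,1/2,3
DORV repair - IVR,375,12,3.20,3.09,2,3,3,4
Ebstein anomaly repair,106,1,0.94,1.17,2,3,3,4
Excision of cardiac tumor,96,2,2.08,2.39,2,3,3,4
Exicion of intracardiac vegetation,11,0,0,1.22,2,2,2,2
Fontan operation - I stage,110,4,3.64,2.97,2,3,3,2
Hemitruncus repair,21,0,0,1.02,2,4,4,2
PDA closure (CPB),32,0,0,0.82,2,1,1,2
PDA closure (off pump),386,6,1.55,1.62,2,1,1,2
Pacemaker - re-implant,8,0,0,1.34,2,1,1,1
Pericardectomy,20,0,0,0.99,2,1,1,2
Pericardial drainage,160,8,5,3.26,2,1,1,4
Pulm. Infundibulum incision & resection,46,1,2.17,1.99,2,2,2,1
Pulmonary art. sling repair,20,0,0,0.96,2,3,3,3
Pulmonary art. stent,13,0,0,1.17,2,2,2,2
Pulmonary arterioplasty,251,8,3.19,3.42,2,2,2,2
Pulmonary valvotomy,200,3,1.50,1.29,2,2,2,2
Pulmonary valvotomy - hybrid,5,0,0,1.43,2,2,2,2
Subaortic septal patch (Konno),15,0,0,1.05,2,4,4,3
Supravalve mitral ring resection,28,0,0,0.79,2,3,3,2
Systemic vein repair,14,0,0,1.12,2,2,2,3
TAPVD repair - intracardiac,184,2,1.09,1.32,2,4,2/4,4
TAPVD repair - mixed type,34,1,2.94,2.67,2,4,2/4,4
Tetralogy repair,2392,46,1.92,1.95,2,2,2,2
Tricuspid replacement (mech.),13,0,0,1.17,2,3,3,2
VSD Hybrid repair (off pump),171,1,0.58,0.84,2,2,2,2
VSD hybrid repair (CPB),21,0,0,0.99,2,2,2,2
VSD multiple repair,127,2,1.57,1.75,2,2,2,2
VSD muscular repair,105,1,0.95,1.20,2,2,2,1
VSD repair - minimal invasive & CPB,45,0,0,0.71,2,2,2,2
AVSD repair - two patches,269,15,5.58,5.27,3,3,3,3
Ao translocation operation,17,2,11.76,4.60,3,3,3,3
Aortic arch repair,70,5,7.14,6.30,3,4,4,4
Aortic valve replacement (mech.),45,3,6.67,4.46,3,3,3,1
Cavopulmonary shunt - bilateral,102,6,5.88,4.61,3,2,2,2
DOLV repair,4,0,0,2.05,3,3,3,4
Delayed sternal closure,891,51,5.72,6.23,3,1,1,1
Double switch (Senning + Rastelli),3,0,0,1.80,3,4,4,5
Excision of cardiac diverticulum,4,0,0,1.53,3,2,2,2
Fontan operation - II stage,537,30,5.59,5.77,3,3,3,2
Kawashima procedure,4,0,0,2.05,3,3,3,1
Mitral replacement (mech.),96,11,11.46,7.86,3,3,3,4
PA banding,101,12,11.88,3.78,3,3,3,4
Pulm. infundibulum resection & patch,78,4,5.13,4.48,3,2,2,1
"Pulm. infundibulum resection, patch across annulus",292,15,5.14,6.09,3,2,2,2
Pulm. vein stenosis repair,40,2,5,5,3,4,4,4
Pulmonary atresia/IVS repair,19,2,10.53,4.87,3,4,4,3
Pulmonary atresia/VSD repair,288,17,5.90,6.24,3,4,4,3
Pulmonary valvotomy (off pump),18,1,5.56,4.60,3,2,2,2
Senning procedure,19,1,5.26,4.34,3,3,3,4
TAPVD repair - supracardiac,238,13,5.46,5.77,3,4,2/4,4
ALC-PA repair,58,10,17.24,14.97,4,3,3,2
Cavopulmonary shunt - left,83,11,13.25,12.68,4,2,2,1
Cavopulmonary shunt - right,359,35,9.75,10.85,4,2,2,1
Central shunt - with graft,38,8,21.05,11.02,4,3,3,4
Conduit RV - PA,72,13,18.06,13.98,4,2,2,3
Double Switch (Hemi-Mustard),6,1,16.67,9.32,4,4,4,5
Interrupted aortic arch repair,77,11,14.29,13.32,4,5,5,4
Interruption of bronchial collaterals,8,1,12.50,9.32,4,1,1,2
Pacemaker - primary implant,17,2,11.76,11.95,4,1,1,1
R.E.V. RV - PA connection,7,1,14.29,8.28,4,4,4,3
Rastelli operation,50,6,12,9.44,4,4,4,3
Rt. or lt. heart assist,8,3,37.50,9.32,4,2,2,1
TAPVD repair - infracardiac,43,6,13.95,14.74,4,4,2/4,4
Takedown previous shunt,11,1,9.09,6.80,4,2,2,3
Arterial switch repair,456,87,19.08,19.20,5,3,3,3
Atrial septectomy,12,4,33.33,27.36,5,4,4,4
Coronary artery repair,6,2,33.33,24,5,3,3,2
DKS connection,9,4,44.44,30.71,5,6,6,5
Double switch (Senning + ASO),18,6,33.33,18.03,5,4,4,5
Fontan takedown,9,5,55.56,41.71,5,3,3,3
Norwood operation,4,3,75,50.76,5,6,6,5
PA debanding,3,1,33.33,16.53,5,3,3,4
PA unifocalization,61,11,18.03,21,5,4,4,4
Truncus repair,33,7,21.21,20.44,5,4,4,4
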