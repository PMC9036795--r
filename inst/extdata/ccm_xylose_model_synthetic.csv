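# Synthetic reconstruction of a yeast central-carbon-metabolism network with
# carbon atom transitions, plus the five-reaction oxidoreductase xylose
# extension (xylose transport, xylose reductase, xylitol dehydrogenase,
# xylulokinase, xylitol export). Lumped steps: PGI/FBA/GAPDH lump adjacent
# glycolytic reactions; CS lumps citrate synthase/aconitase/isocitrate
# dehydrogenase; TCA lumps the remaining cycle back to oxaloacetate
# (succinate scrambling omitted). Biomass drains are per-precursor sinks.
# columns: id,equation,reversible,block,alias
id,equation,reversible,block,alias
XYLt,XYL.ext (abcde) -> XYL (abcde),FALSE,xylose_extension,R25
XR,XYL (abcde) -> XOL (abcde),FALSE,xylose_extension,R48
XDH,XOL (abcde) -> XUL (abcde),FALSE,xylose_extension,R49
XK,XUL (abcde) -> X5P (abcde),FALSE,xylose_extension,R50
XOLt,XOL (abcde) -> XOL.ext (abcde),FALSE,xylose_extension,R59
RPE,Ru5P (abcde) -> X5P (abcde),TRUE,base_model,
RPI,Ru5P (abcde) -> R5P (abcde),TRUE,base_model,
TKT1,X5P (abcde) + R5P (fghij) -> GAP (cde) + S7P (abfghij),TRUE,base_model,
TAL,S7P (abcdefg) + GAP (hij) -> E4P (defg) + F6P (abchij),TRUE,base_model,
TKT2,X5P (abcde) + E4P (fghi) -> GAP (cde) + F6P (abfghi),TRUE,base_model,
PGI,G6P (abcdef) -> F6P (abcdef),TRUE,base_model,
FBA,F6P (abcdef) -> GAP (cba) + GAP (def),TRUE,base_model,
GAPDH,GAP (abc) -> PG3 (abc),TRUE,base_model,
PYK,PG3 (abc) -> PYR (abc),FALSE,base_model,
G6PDH,G6P (abcdef) -> PG6 (abcdef),FALSE,base_model,
GND,PG6 (abcdef) -> CO2 (a) + Ru5P (bcdef),FALSE,base_model,
PDH,PYR (abc) -> CO2 (a) + ACA (bc),FALSE,base_model,
PC,PYR (abc) + CO2 (d) -> OAA (abcd),FALSE,base_model,
CS,OAA (abcd) + ACA (ef) -> AKG (dcbfe) + CO2 (a),FALSE,base_model,
TCA,AKG (abcde) -> CO2 (a) + OAA (bcde),FALSE,base_model,
G6Pase,G6P (abcdef) -> GLC (abcdef),FALSE,base_model,
GLCt,GLC (abcdef) -> GLC.ext (abcdef),FALSE,base_model,
CO2t,CO2 (a) -> CO2.ext (a),FALSE,base_model,
BM_R5P,R5P (abcde) -> R5P.bio (abcde),FALSE,biomass,
BM_E4P,E4P (abcd) -> E4P.bio (abcd),FALSE,biomass,
BM_G6P,G6P (abcdef) -> G6P.bio (abcdef),FALSE,biomass,
BM_GAP,GAP (abc) -> GAP.bio (abc),FALSE,biomass,
BM_PG3,PG3 (abc) -> PG3.bio (abc),FALSE,biomass,
BM_PYR,PYR (abc) -> PYR.bio (abc),FALSE,biomass,
BM_ACA,ACA (ab) -> ACA.bio (ab),FALSE,biomass,
BM_OAA,OAA (abcd) -> OAA.bio (abcd),FALSE,biomass,
BM_AKG,AKG (abcde) -> AKG.bio (abcde),FALSE,biomass,
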