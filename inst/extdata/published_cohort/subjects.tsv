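subject_id	family_id	sex	eva
YUEVA38	YUEVA38	male	TRUE
YUEVA59	YUEVA59	male	TRUE
YUEVA60	YUEVA60	male	TRUE
YUEVA61	YUEVA61	female	TRUE
YUEVA65	YUEVA65	male	TRUE
YUEVA67	YUEVA67	male	TRUE
YUEVA69	YUEVA69	male	TRUE
YUEVA72	YUEVA72	male	TRUE
YUEVA73	YUEVA73	male	TRUE
YUEVA74	YUEVA74	female	TRUE
YUEVA77	YUEVA77	female	TRUE
YUEVA111	YUEVA111	male	TRUE
YUHL6-21	YUHL6	female	FALSE
YUHL11-21	YUHL11	male	FALSE
YUHL19-21	YUHL19	female	FALSE
YUHL8-21	YUHL8	female	FALSE
YUHL13-21	YUHL13	male	FALSE
YUHL24-21	YUHL24	female	FALSE
YUHL10-21	YUHL10	male	FALSE
YUHL14-21	YUHL14	female	FALSE
YUHL20-21	YUHL20	male	FALSE
YUHL26-21	YUHL26	female	FALSE
YUHL30-21	YUHL30	female	FALSE
YUHL33-21	YUHL33	female	FALSE
YUHL36-21	YUHL36	male	FALSE
YUHL40-21	YUHL40	female	FALSE
YUHL44-21	YUHL44	male	FALSE
YUHL45-21	YUHL45	female	FALSE
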