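code,indicator,response_type,level,color,note
G1,Access to the fishery,categorical,open_access,red,"Open access erodes stewardship incentives; rights-based access (TURF, permits, quotas) supports them"
G1,Access to the fishery,categorical,managed_access,green,"Rights-based access (TURF, permits, quotas) promotes stewardship"
G2,Number of fishers,ordinal,increasing,red,Growing effort raises pressure on the reserve and surrounding TURF
G2,Number of fishers,ordinal,stable,green,Stable effort indicates controlled entry
G2,Number of fishers,ordinal,decreasing,green,Declining effort reduces pressure
G3,Legal recognition of reserve,binary,yes,green,Formal recognition strengthens enforcement and permanence
G3,Legal recognition of reserve,binary,no,red,Unrecognized reserves depend entirely on voluntary compliance
G4,Reserve type,descriptive,,,Narrative entry; presented in the report but not scored
G5,Illegal harvesting,ordinal,none,green,Absence of poaching is a positive factor
G5,Illegal harvesting,ordinal,low,green,Low perceived poaching is a positive factor
G5,Illegal harvesting,ordinal,medium,red,Perceptible poaching undermines protection
G5,Illegal harvesting,ordinal,high,red,High perceived illegal fishing is a negative factor
G6,Management plan,binary,yes,green,A written management plan supports consistent rules
G6,Management plan,binary,no,red,Absence of a plan leaves rules informal
G7,Reserve enforcement,descriptive,,,Narrative entry; presented in the report but not scored
G8,Size of reserve,ordinal,adequate,green,Reserve large enough to protect target species' movements
G8,Size of reserve,ordinal,inadequate,red,Reserve too small relative to target species' mobility
G9,Reasoning for reserve location,descriptive,,,Narrative entry; presented in the report but not scored
G10,Membership to fisher organizations,binary,yes,green,Organized fishers coordinate rules and surveillance
G10,Membership to fisher organizations,binary,no,red,Unorganized harvesters weaken collective action
G11,Type of fisheries organizations,categorical,none,red,No collective structure to carry management
G11,Type of fisheries organizations,categorical,cooperative,green,Cooperatives foster communication and cooperation
G11,Type of fisheries organizations,categorical,cooperative_and_federation,green,Polycentric structures add bargaining power and coordination
G12,Representation,ordinal,low,red,Top-down siting without user input reduces buy-in
G12,Representation,ordinal,medium,green,Partial participation still builds legitimacy
G12,Representation,ordinal,high,green,Bottom-up participatory design builds compliance
G13,Internal regulation,binary,yes,green,Internal rules about the reserve indicate self-governance
G13,Internal regulation,binary,no,red,No internal rules to back the closure
G14,Perceived effectiveness,categorical,negative,red,Negative perception erodes support for the reserve
G14,Perceived effectiveness,categorical,neutral,red,No perceived benefit does not sustain support
G14,Perceived effectiveness,categorical,positive,green,Perceived benefits sustain compliance and support
G15,Social impact of reserve,categorical,negative,red,Social conflict or cost attributed to the reserve
G15,Social impact of reserve,categorical,neutral,red,No social benefit attributed to the reserve
G15,Social impact of reserve,categorical,positive,green,Social capital and pride attributed to the reserve
B5,Natural disturbance,descriptive,,,Narrative entry; presented in the report but not scored
S3,Alternative economic opportunities,ordinal,none,red,No fallback livelihood concentrates pressure on the fishery
S3,Alternative economic opportunities,ordinal,few,red,Scarce alternatives keep pressure high
S3,Alternative economic opportunities,ordinal,some,green,Alternatives buffer income during closures
S3,Alternative economic opportunities,ordinal,many,green,Diversified livelihoods reduce fishing pressure
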