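scheme_id	regulator	target	mode
scheme01	orm	SPT	inhibition
scheme02	orm	SPT	inhibition
scheme02	orm	CSI	activation
scheme03	orm	SPT	inhibition
scheme03	orm	CSI	inhibition
scheme04	orm	SPT	inhibition
scheme04	orm	CSII	activation
scheme05	orm	SPT	inhibition
scheme05	orm	CSI	activation
scheme05	orm	CSII	activation
scheme06	orm	SPT	inhibition
scheme06	orm	CSI	inhibition
scheme06	orm	CSII	activation
scheme07	orm	SPT	inhibition
scheme07	orm	CSII	inhibition
scheme08	orm	SPT	inhibition
scheme08	orm	CSI	activation
scheme08	orm	CSII	inhibition
scheme09	orm	SPT	inhibition
scheme09	orm	CSI	inhibition
scheme09	orm	CSII	inhibition
scheme10	orm	SPT	inhibition
scheme10	ceramide	SPT	inhibition
scheme11	orm	SPT	inhibition
scheme11	orm	CSI	activation
scheme11	ceramide	SPT	inhibition
scheme12	orm	SPT	inhibition
scheme12	orm	CSI	inhibition
scheme12	ceramide	SPT	inhibition
scheme13	orm	SPT	inhibition
scheme13	orm	CSII	activation
scheme13	ceramide	SPT	inhibition
scheme14	orm	SPT	inhibition
scheme14	orm	CSI	activation
scheme14	orm	CSII	activation
scheme14	ceramide	SPT	inhibition
scheme15	orm	SPT	inhibition
scheme15	orm	CSI	inhibition
scheme15	orm	CSII	activation
scheme15	ceramide	SPT	inhibition
scheme16	orm	SPT	inhibition
scheme16	orm	CSII	inhibition
scheme16	ceramide	SPT	inhibition
scheme17	orm	SPT	inhibition
scheme17	orm	CSI	activation
scheme17	orm	CSII	inhibition
scheme17	ceramide	SPT	inhibition
scheme18	orm	SPT	inhibition
scheme18	orm	CSI	inhibition
scheme18	orm	CSII	inhibition
scheme18	ceramide	SPT	inhibition
scheme19	orm	SPT	inhibition
scheme19	ceramide	CSI	inhibition
scheme20	orm	SPT	inhibition
scheme20	ceramide	CSII	inhibition
scheme21	orm	SPT	inhibition
scheme21	ceramide	orm	inhibition
scheme21	orm	CSII	activation
scheme22	orm	SPT	inhibition
scheme22	ceramide	orm	inhibition
scheme22	orm	CSII	activation
scheme22	orm	CSI	inhibition
scheme23	orm	SPT	inhibition
scheme23	ceramide	orm	inhibition
scheme23	orm	CSII	activation
scheme23	ceramide	SPT	inhibition
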