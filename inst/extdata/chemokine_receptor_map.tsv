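ligand	receptor	source
CCL1	CCR8	literature-consensus
CCL2	CCR2	literature-consensus
CCL2	CCR4	literature-consensus
CCL3	CCR1	literature-consensus
CCL3	CCR5	literature-consensus
CCL4	CCR5	literature-consensus
CCL5	CCR1	literature-consensus
CCL5	CCR3	literature-consensus
CCL5	CCR5	literature-consensus
CCL7	CCR1	literature-consensus
CCL7	CCR2	literature-consensus
CCL7	CCR3	literature-consensus
CCL8	CCR1	literature-consensus
CCL8	CCR2	literature-consensus
CCL8	CCR3	literature-consensus
CCL8	CCR5	literature-consensus
CCL11	CCR3	literature-consensus
CCL13	CCR1	literature-consensus
CCL13	CCR2	literature-consensus
CCL13	CCR3	literature-consensus
CCL14	CCR1	literature-consensus
CCL15	CCR1	literature-consensus
CCL15	CCR3	literature-consensus
CCL16	CCR1	literature-consensus
CCL16	CCR2	literature-consensus
CCL17	CCR4	literature-consensus
CCL19	CCR7	literature-consensus
CCL20	CCR6	literature-consensus
CCL21	CCR7	literature-consensus
CCL22	CCR4	literature-consensus
CCL23	CCR1	literature-consensus
CCL24	CCR3	literature-consensus
CCL25	CCR9	literature-consensus
CCL26	CCR3	literature-consensus
CCL27	CCR10	literature-consensus
CCL28	CCR3	literature-consensus
CCL28	CCR10	literature-consensus
CXCL1	CXCR2	literature-consensus
CXCL2	CXCR2	literature-consensus
CXCL3	CXCR2	literature-consensus
CXCL5	CXCR2	literature-consensus
CXCL6	CXCR1	literature-consensus
CXCL6	CXCR2	literature-consensus
CXCL8	CXCR1	literature-consensus
CXCL8	CXCR2	literature-consensus
CXCL9	CXCR3	literature-consensus
CXCL10	CXCR3	literature-consensus
CXCL11	CXCR3	literature-consensus
CXCL12	CXCR4	literature-consensus
CXCL12	ACKR3	literature-consensus
CXCL13	CXCR5	literature-consensus
CXCL16	CXCR6	literature-consensus
CX3CL1	CX3CR1	literature-consensus
XCL1	XCR1	literature-consensus
XCL2	XCR1	literature-consensus
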