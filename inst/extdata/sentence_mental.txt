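V4AV2SV5LV3AAVLV1SV2SV2SV6LV4AV4AV4AAVFAVRLd2V6LV3AV1SLd1V5LV5LV5LLd2AVLV2SV3AAVFLd3V1SLd3AVLV2SV6LV6LLd1AVLV3AV4AV2SV4ALd1Ld2Ld2V5LV3AV3ALd3V4AV4AAVLV4AAVRV1SLd2AVLAVLV2SAVLAVFLd1Ld3AVFAVRLd2AVRAVFV2SV5LAVLV4AAVRAVRV5LV1SV1SV1SAVLLd3Ld3V5LV2SAVRV5LAVLV6LLd1AVRAVLV4AV1SAVRV3AV5LLd3V2SLd3Ld3AVRAVRV2SLd3V6LAVFV2SLd1Ld1V4AV5LAVFAVFV3AAVLV5LV2SV3AAVRLd3Ld1AVFV4ALd1Ld3V6LLd3V3ALd1AVLLd2Ld1V4AAVLLd1V1SV3AAVLV3ALd2AVRV1SV2SV6LLd2AVFV5LV5LLd1V6LV2SAVFV3AAVRV5LV1SAVLLd3V3AAVRV4AV2SV6LV1SLd1V2SAVFAVRV1SV1SV5LAVFV1SV5LV6LLd3Ld3V5LAVRLd2V2SLd2V3ALd3AVLLd1AVRV1SAVRLd1V1S
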